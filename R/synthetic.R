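## Synthetic corpus generator.
##
## Generates standoff corpora with planted ground truth so that every
## pipeline stage can be tested without any external data: documents are
## deterministic token templates ("GENE trigger GENE ...") — linguistic
## realism is not the goal, offset correctness is.  Event structures are
## drawn from a mixture over the prevalent coarse patterns observed in
## large-scale event data; gene surfaces are optionally decorated with
## affixes and spelling variants that the canonicalizer must undo; raw
## classifier margins are sampled per trigger and argument.  The planted
## answers (canonical symbols, refined structures, pairs, indirect
## associations) are computed by an intentionally naive, separate
## implementation of the pairwise walk, not by the main extractor.

#' Default event-pattern mixture
#'
#' The nine prevalent coarse event patterns with their observed
#' occurrence shares (58.6, 15.0, 8.4, 8.0, 4.7, 3.8, 0.2, 0.2, 0.2
#' percent, renormalized to sum to one).
#'
#' @return Named numeric vector: signature pattern -> probability.
#' @export
default_pattern_mixture <- function() {
  w <- c("Phy(T:A)"                              = 58.6,
         "*Reg(T:A)"                             = 15.0,
         "*Reg(T:Phy(T:A))"                      = 8.4,
         "Bind(T:A, T:B)"                        = 8.0,
         "*Reg(C:A, T:B)"                        = 4.7,
         "*Reg(C:A, T:Phy(T:B))"                 = 3.8,
         "*Reg(C:*Reg(T:Phy(T:A)), T:Phy(T:B))"  = 0.2,
         "*Reg(C:Phy(T:A), T:B)"                 = 0.2,
         "*Reg(C:Phy(T:A), T:Phy(T:B))"          = 0.2)
  w / sum(w)
}

#' Default gene pool
#'
#' Twenty canonical symbols with frequency-skewed sampling weights
#' (roughly Zipfian) and a demo family assignment in which the frequent
#' symbols are family-mapped and the long tail is not — mirroring the
#' situation where a small fraction of distinct symbols covers most
#' occurrences.
#'
#' @return A data.frame with columns `symbol`, `family` (`NA` when
#'   unmapped), `weight`.
#' @export
default_gene_pool <- function() {
  symbols <- c("mec1", "rad9", "rad53", "atr", "esr1", "akt1", "mapk1",
               "il2", "nfkb1", "p55", "egf", "thrombin", "p21", "bzr1",
               "s6k", "ent1", "cab2", "hsf1", "dun1", "sml1")
  family <- c("FAM01", "FAM02", "FAM03", "FAM01", "FAM04", "FAM05", "FAM06",
              "FAM07", "FAM08", NA, NA, NA, NA, NA,
              NA, NA, NA, NA, NA, NA)
  data.frame(symbol = symbols, family = family,
             weight = 1 / seq_along(symbols), stringsAsFactors = FALSE)
}

#' Demo family scheme over the default gene pool
#'
#' @param pool A gene pool data.frame (see [default_gene_pool()]).
#' @return A `family_scheme` named `"families_demo"`.
#' @export
default_family_scheme <- function(pool = default_gene_pool()) {
  mapped <- pool[!is.na(pool$family), , drop = FALSE]
  family_scheme("families_demo", mapped$symbol, mapped$family,
                provenance = "synthetic demo mapping")
}

#' Generator configuration
#'
#' @param n_documents Number of documents to generate.
#' @param pattern_mixture Named probability vector over signature
#'   patterns (must sum to 1); see [default_pattern_mixture()].
#' @param gene_pool Gene pool data.frame; see [default_gene_pool()].
#' @param score_model Per-kind mean/sd of raw classifier margins.
#' @param decorate_prob Probability that a mention surface is decorated
#'   with affixes/spelling variants.
#' @param chain_prob Probability that a regulation-rooted structure gets
#'   1–2 extra Cause-less regulation layers spliced in above its Theme
#'   (the raw material of the refinement rewrite).
#' @param events_per_doc Integer vector to sample the per-document
#'   structure count from.
#' @param seed Integer seed; a fixed seed makes the output
#'   byte-identical across runs.
#' @return A `generator_config`.
#' @export
generator_config <- function(n_documents = 50,
                             pattern_mixture = default_pattern_mixture(),
                             gene_pool = default_gene_pool(),
                             score_model = list(
                               trigger = list(mean = 0.8, sd = 1.0),
                               argument = list(mean = 1.2, sd = 0.7)),
                             decorate_prob = 0.3,
                             chain_prob = 0.25,
                             events_per_doc = 1:3,
                             seed = 1L) {
  if (abs(sum(pattern_mixture) - 1) > 1e-8)
    stop("pattern mixture probabilities must sum to 1", call. = FALSE)
  if (any(pattern_mixture < 0))
    stop("pattern mixture probabilities must be non-negative", call. = FALSE)
  structure(list(n_documents = n_documents, pattern_mixture = pattern_mixture,
                 gene_pool = gene_pool, score_model = score_model,
                 decorate_prob = decorate_prob, chain_prob = chain_prob,
                 events_per_doc = events_per_doc, seed = as.integer(seed)),
            class = "generator_config")
}

## Instantiate a signature pattern into a concrete event tree: every
## "*Reg" gets a sampled regulation polarity, "Phy" a sampled physical
## type, "Bind" becomes binding; placeholder letters become gene slots.
instantiate_pattern <- function(pattern) {
  s <- pattern
  while (grepl("*Reg", s, fixed = TRUE)) {
    sub1 <- sample(c("Regulation", "Positive-Regulation", "Negative-Regulation"), 1)
    s <- sub("*Reg", sub1, s, fixed = TRUE)
  }
  while (grepl("Phy(", s, fixed = TRUE)) {
    sub1 <- sample(c("Gene-Expression", "Transcription", "Localization",
                     "Protein-Catabolism", "Phosphorylation"), 1)
    s <- sub("Phy(", paste0(sub1, "("), s, fixed = TRUE)
  }
  s <- gsub("Bind(", "Binding(", s, fixed = TRUE)
  parse_bracket(s)
}

## Substitute sampled symbols for placeholder leaves, in place.
substitute_genes <- function(node, mapping) {
  if (!is_event_node(node)) {
    node$symbol <- unname(mapping[node$symbol])
    return(node)
  }
  node$children <- lapply(node$children, substitute_genes, mapping = mapping)
  node
}

## Decorate a canonical symbol into a surface the canonicalizer must
## undo: optional case/hyphen variant of the core, optional affixes.
decorate_surface <- function(symbol, decorate) {
  core <- symbol
  if (stats::runif(1) < 0.5)
    core <- paste0(toupper(substring(core, 1, 1)), substring(core, 2))
  if (stats::runif(1) < 0.3 && grepl("[a-zA-Z][0-9]+$", core))
    core <- sub("([0-9]+)$", "-\\1", core)
  if (!decorate) return(core)
  lex <- default_affix_lexicon()
  parts <- core
  if (stats::runif(1) < 0.7)
    parts <- c(sample(lex$prefixes, 1), parts)
  if (stats::runif(1) < 0.7)
    parts <- c(parts, sample(lex$suffixes, 1))
  paste(parts, collapse = " ")
}

TRIGGER_WORDS <- list(
  gene_expression = "expressed", transcription = "transcribed",
  localization = "localized", protein_catabolism = "degraded",
  phosphorylation = "phosphorylated", binding = "binds",
  regulation = "regulates", positive_regulation = "activates",
  negative_regulation = "inhibits")

## Wrap extra Cause-less regulation layers between a regulation root and
## its Theme argument, returning the chained tree and the chain types.
splice_chain <- function(tree, depth) {
  ti <- which(tree$roles == "Theme")
  inner <- tree$children[[ti]]
  types <- sample(REGULATION_TYPES, depth, replace = TRUE)
  for (ty in rev(types))
    inner <- ev_event(ty, "Theme", list(inner))
  tree$children[[ti]] <- inner
  list(tree = tree, chain = types)
}

## Independent expected refined root type: fold the chain into the root
## polarity with the one-change budget, using the rule table directly.
expected_chain_type <- function(root_type, chain) {
  ty <- root_type; changes <- 0L
  for (nested in chain) {
    comp <- compose_polarity(ty, nested)
    if (comp$is_type_change) {
      if (changes >= 1L) ty <- "regulation"
      else { ty <- comp$result; changes <- changes + 1L }
    } else ty <- comp$result
  }
  ty
}

#' Generate a synthetic standoff corpus with planted ground truth
#'
#' @param config A `generator_config`.
#' @param dir Optional directory: when given, the corpus is written in
#'   the standoff dialect (plus `ground_truth.json`) there.
#' @return A list with `corpus` (a `standoff_corpus`, raw scores
#'   attached), `ground_truth` (planted canonical symbols, refined
#'   structures, aggregated pairs and indirect associations under the
#'   canonical scheme), and `dir` (when written).
#' @export
generate_corpus <- function(config = generator_config(), dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  pool <- config$gene_pool
  docs <- list()
  truth_canonical <- list()       # surface -> planted canonical symbol
  truth_refined <- list()         # doc -> event id -> bracket string
  seed_rows <- list()             # per-occurrence naive pair seeds

  for (d in seq_len(config$n_documents)) {
    doc_id <- sprintf("doc%05d", d)
    n_struct <- if (length(config$events_per_doc) == 1L) config$events_per_doc
                else sample(config$events_per_doc, 1)
    mentions <- empty_mentions()
    events <- list()
    tokens <- character(0)
    tok_start <- integer(0)
    cursor <- 0L
    mention_i <- 0L; trigger_i <- 0L; event_i <- 0L
    trig_lines_meta <- list()
    refined_here <- list()

    push_token <- function(txt) {
      if (cursor > 0L) cursor <<- cursor + 1L  # joining space
      start <- cursor
      tokens <<- c(tokens, txt)
      tok_start <<- c(tok_start, start)
      cursor <<- cursor + nchar(txt)
      start
    }

    for (s in seq_len(n_struct)) {
      pattern <- sample(names(config$pattern_mixture), 1,
                        prob = config$pattern_mixture)
      tree <- instantiate_pattern(pattern)
      placeholders <- unique(tree_gene_symbols(tree))
      idx <- sample.int(nrow(pool), length(placeholders), prob = pool$weight)
      mapping <- structure(pool$symbol[idx], names = placeholders)
      tree <- substitute_genes(tree, mapping)

      chain <- character(0)
      if (is_regulation_type(tree$type) &&
          stats::runif(1) < config$chain_prob) {
        sp <- splice_chain(tree, sample(1:2, 1))
        expected_type <- expected_chain_type(tree$type, sp$chain)
        expected <- tree; expected$type <- expected_type
        tree <- sp$tree
        chain <- sp$chain
      } else {
        expected <- tree
      }

      ## linearize: emit each event's trigger then its arguments
      emit <- function(node) {
        if (!is_event_node(node)) {
          mention_i <<- mention_i + 1L
          mid <- paste0("T", mention_i)
          surface <- decorate_surface(node$symbol,
                                      stats::runif(1) < config$decorate_prob)
          start <- push_token(surface)
          mentions <<- rbind(mentions, data.frame(
            mention_id = mid, start = start, end = start + nchar(surface),
            surface = surface, canonical = NA_character_,
            stringsAsFactors = FALSE))
          truth_canonical[[surface]] <<- node$symbol
          node$mention_id <- mid
          return(node)
        }
        word <- TRIGGER_WORDS[[node$type]]
        start <- push_token(word)
        node$trigger <- word
        node$trigger_start <- start
        node$children <- lapply(node$children, emit)
        node
      }
      tree <- emit(tree)

      ## flatten the tree into event records (preorder event ids)
      flatten <- function(node) {
        event_i <<- event_i + 1L
        eid <- paste0("E", event_i)
        node$event_id <- eid
        events[[eid]] <<- list()  # reserve preorder slot
        targets <- character(0)
        kids <- list()
        for (k in seq_along(node$children)) {
          ch <- node$children[[k]]
          if (is_event_node(ch)) {
            ch <- flatten(ch)
            targets <- c(targets, ch$event_id)
          } else {
            targets <- c(targets, ch$mention_id)
          }
          kids[[k]] <- ch
        }
        node$children <- kids
        events[[eid]] <<- list(
          event_id = eid, type = node$type,
          trigger_start = node$trigger_start,
          trigger_end = node$trigger_start + nchar(node$trigger),
          trigger_text = node$trigger,
          roles = node$roles, targets = targets,
          trigger_score = stats::rnorm(1, config$score_model$trigger$mean,
                                       config$score_model$trigger$sd),
          arg_scores = stats::rnorm(length(node$roles),
                                    config$score_model$argument$mean,
                                    config$score_model$argument$sd),
          norm_score = NA_real_)
        node
      }
      tree <- flatten(tree)
      root_id <- tree$event_id

      ## planted refined structure for this root
      truth_refined[[doc_id]][[root_id]] <- print_bracket_keyed(expected, tree)
      refined_here[[root_id]] <- expected

      ## planted pair seeds via the naive walker, on the expected refined
      ## structure with canonical keys
      seeds <- naive_pair_walk(attach_keys(expected, tree))
      if (nrow(seeds)) {
        seeds$doc_id <- doc_id
        seeds$event_id <- root_id
        seed_rows[[length(seed_rows) + 1L]] <- seeds
      }
    }

    text <- paste(tokens, collapse = " ")
    docs[[doc_id]] <- new_document(doc_id, text, mentions, events)
  }
  corpus <- structure(docs, class = "standoff_corpus")

  planted_pairs <- naive_aggregate(seed_rows)
  planted_assocs <- naive_join(planted_pairs,
                               do.call(rbind, c(list(empty_capture()), seed_rows)))

  ground_truth <- list(
    seed = config$seed,
    n_documents = config$n_documents,
    canonical = truth_canonical[order(names(truth_canonical))],
    refined = truth_refined,
    pairs = planted_pairs,
    associations = planted_assocs)

  if (!is.null(dir)) {
    write_corpus(corpus, dir)
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(corpus = corpus, ground_truth = ground_truth, dir = dir)
}

## The expected refined tree mirrors the generated tree minus spliced
## chain layers; leaves line up one-to-one in traversal order, so keys
## (planted canonical symbols) can be carried over positionally.
attach_keys <- function(expected, generated) {
  exp_leaves <- tree_genes(expected)
  gen_leaves <- tree_genes(generated)
  stopifnot(length(exp_leaves) == length(gen_leaves))
  i <- 0L
  walk <- function(node) {
    if (!is_event_node(node)) {
      i <<- i + 1L
      node$mention_id <- gen_leaves[[i]]$mention_id
      return(node)
    }
    node$children <- lapply(node$children, walk)
    node
  }
  walk(expected)
}

## Bracket string of the expected refined structure (symbols only).
print_bracket_keyed <- function(expected, generated) print_bracket(expected)

empty_capture <- function() {
  df <- empty_pair_seeds()
  df$doc_id <- character(0); df$event_id <- character(0)
  df
}

## ---- the naive oracle -----------------------------------------------------

## A literal, per-pair implementation of the three classification steps,
## deliberately separate from the main extractor: for each unordered
## pair of gene leaves it searches the joining event by subtree
## membership and evaluates the reclassification conditions with
## recursive predicates.

node_contains_leaf <- function(node, leaf) {
  if (!is_event_node(node)) return(identical(node, leaf))
  for (ch in node$children) if (node_contains_leaf(ch, leaf)) return(TRUE)
  FALSE
}

## All event nodes of a tree, with subtree sizes.
all_event_nodes <- function(node) {
  if (!is_event_node(node)) return(list())
  c(list(node), unlist(lapply(node$children, all_event_nodes), recursive = FALSE))
}

## Does `leaf` sit below `node` with at least one Theme step on the way?
reached_via_theme <- function(node, leaf, theme_seen = FALSE) {
  if (!is_event_node(node)) return(identical(node, leaf) && theme_seen)
  for (k in seq_along(node$children)) {
    if (reached_via_theme(node$children[[k]], leaf,
                          theme_seen || node$roles[k] == "Theme"))
      return(TRUE)
  }
  FALSE
}

## Does `leaf` sit below `node` with at least one Cause step on the way?
reached_via_cause <- function(node, leaf, cause_seen = FALSE) {
  if (!is_event_node(node)) return(identical(node, leaf) && cause_seen)
  for (k in seq_along(node$children)) {
    if (reached_via_cause(node$children[[k]], leaf,
                          cause_seen || node$roles[k] == "Cause"))
      return(TRUE)
  }
  FALSE
}

## Deepest event on the path from `node` to `leaf` at which the leaf is
## a Cause-descendant; used to find the coregulation target.
deepest_cause_event <- function(node, leaf) {
  if (!is_event_node(node)) return(NULL)
  for (k in seq_along(node$children)) {
    ch <- node$children[[k]]
    if (node_contains_leaf(ch, leaf)) {
      below <- deepest_cause_event(ch, leaf)
      if (!is.null(below)) return(below)
      if (node$roles[k] == "Cause") return(node)
      return(NULL)
    }
  }
  NULL
}

#' Naive reference implementation of the pairwise walk
#'
#' A deliberately simple per-pair implementation of the pairwise
#' classification steps, used as the independent oracle for the main
#' extractor and to plant ground truth in generated corpora.  Not meant
#' for production use.
#'
#' @param root An event tree whose leaves carry symbols (keys).
#' @return A seed data.frame in the shape of [extract_pairs()].
#' @export
naive_pair_walk <- function(root) {
  ## tag every leaf with a unique occurrence id so that two mentions of
  ## the same symbol are distinguishable by identical()
  uid <- 0L
  tag <- function(node) {
    if (!is_event_node(node)) {
      uid <<- uid + 1L
      node$occurrence <- uid
      return(node)
    }
    node$children <- lapply(node$children, tag)
    node
  }
  root <- tag(root)
  leaves <- tree_genes(root)
  if (length(leaves) < 2L) return(empty_pair_seeds())
  events <- all_event_nodes(root)
  sizes <- vapply(events, tree_event_count, integer(1))

  acc <- list()
  add <- function(key_a, key_b, cls, directed, target = NA_character_) {
    acc[[length(acc) + 1L]] <<- c(key_a, key_b, cls,
                                  if (directed) "T" else "F", target)
  }

  n <- length(leaves)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    la <- leaves[[i]]; lb <- leaves[[j]]
    if (is.na(la$symbol) || is.na(lb$symbol) ||
        identical(la$symbol, lb$symbol)) next
    ## joining event: smallest event subtree containing both leaves
    holds <- vapply(events, function(e)
      node_contains_leaf(e, la) && node_contains_leaf(e, lb), logical(1))
    if (!any(holds)) next
    join <- events[holds][[which.min(sizes[holds])]]

    ## step 1: binding iff both are direct Themes of one binding event
    direct_theme_of_join <- function(leaf) {
      any(vapply(seq_along(join$children), function(k)
        join$roles[k] == "Theme" && identical(join$children[[k]], leaf),
        logical(1)))
    }
    if (join$type == "binding" &&
        direct_theme_of_join(la) && direct_theme_of_join(lb)) {
      k <- sort(c(la$symbol, lb$symbol))
      add(k[1], k[2], "binding", FALSE)
      next
    }

    ## otherwise a regulation candidate: sort out the Cause/Theme sides
    side_of <- function(leaf) {
      for (k in seq_along(join$children))
        if (node_contains_leaf(join$children[[k]], leaf))
          return(list(role = join$roles[k], sub = join$children[[k]]))
      NULL
    }
    sa <- side_of(la); sb <- side_of(lb)
    if (is.null(sa) || is.null(sb) || sa$role == sb$role) next
    if (sa$role == "Cause") { cl <- la; cs <- sa; tl <- lb; ts <- sb }
    else                    { cl <- lb; cs <- sb; tl <- la; ts <- sa }

    ## step 3: the theme-side gene is a Cause inside the Theme argument
    if (is_event_node(ts$sub) && reached_via_cause(ts$sub, tl)) {
      inner <- deepest_cause_event(ts$sub, tl)
      targets <- character(0)
      for (k in seq_along(inner$roles))
        if (inner$roles[k] == "Theme")
          targets <- c(targets, tree_gene_symbols(inner$children[[k]]))
      targets <- sort(unique(targets))
      targets <- targets[!is.na(targets) &
                         !targets %in% c(cl$symbol, tl$symbol)]
      k <- sort(c(cl$symbol, tl$symbol))
      if (length(targets) == 0L) add(k[1], k[2], "coregulation_capture", FALSE)
      else for (tg in targets) add(k[1], k[2], "coregulation_capture", FALSE, tg)
      next
    }
    ## step 2: the cause-side gene is only reached through a Theme role
    cls <- if (is_event_node(cs$sub) && reached_via_theme(cs$sub, cl))
      "indirect_regulation" else "regulation"
    add(cl$symbol, tl$symbol, cls, TRUE)
  }
  seeds_from_acc(acc)
}

## Aggregate naive per-occurrence seeds into the planted pair table.
naive_aggregate <- function(seed_rows) {
  if (length(seed_rows) == 0L) {
    return(data.frame(key_a = character(0), key_b = character(0),
                      cls = character(0), directed = logical(0),
                      n_evidence = integer(0), stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, seed_rows)
  gid <- paste(ev$key_a, ev$key_b, ev$cls, ev$directed, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(ev)), gid), function(idx) {
    e <- ev[idx, , drop = FALSE]
    data.frame(key_a = e$key_a[1], key_b = e$key_b[1], cls = e$cls[1],
               directed = e$directed[1], n_evidence = nrow(e),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$cls, out$key_a, out$key_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Brute-force triple-loop join over the planted pair table.
naive_join <- function(pairs, all_seeds) {
  rows <- list()
  emit <- function(kind, a, b, z) {
    k <- sort(c(a, b))
    rows[[length(rows) + 1L]] <<- data.frame(kind = kind, key_a = k[1],
                                             key_b = k[2], shared = z,
                                             stringsAsFactors = FALSE)
  }
  reg <- pairs[pairs$cls %in% c("regulation", "indirect_regulation"), ,
               drop = FALSE]
  bind <- pairs[pairs$cls == "binding", , drop = FALSE]
  if (nrow(reg)) for (i in seq_len(nrow(reg))) for (j in seq_len(nrow(reg))) {
    if (i >= j) next
    if (reg$key_b[i] == reg$key_b[j] && reg$key_a[i] != reg$key_a[j])
      emit("coregulation", reg$key_a[i], reg$key_a[j], reg$key_b[i])
    if (reg$key_a[i] == reg$key_a[j] && reg$key_b[i] != reg$key_b[j])
      emit("common_regulator", reg$key_b[i], reg$key_b[j], reg$key_a[i])
  }
  if (!is.null(all_seeds) && nrow(all_seeds)) {
    cap <- all_seeds[all_seeds$cls == "coregulation_capture" &
                     !is.na(all_seeds$target), , drop = FALSE]
    if (nrow(cap)) for (r in seq_len(nrow(cap)))
      emit("coregulation", cap$key_a[r], cap$key_b[r], cap$target[r])
  }
  if (nrow(bind)) {
    half <- rbind(data.frame(g = bind$key_a, z = bind$key_b,
                             stringsAsFactors = FALSE),
                  data.frame(g = bind$key_b, z = bind$key_a,
                             stringsAsFactors = FALSE))
    for (i in seq_len(nrow(half))) for (j in seq_len(nrow(half))) {
      if (i >= j) next
      if (half$z[i] == half$z[j] && half$g[i] != half$g[j])
        emit("common_binding_partner", half$g[i], half$g[j], half$z[i])
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(0), key_a = character(0),
                      key_b = character(0), n_shared = integer(0),
                      shared = character(0), stringsAsFactors = FALSE))
  }
  flat <- unique(do.call(rbind, rows))
  gid <- paste(flat$kind, flat$key_a, flat$key_b, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(flat)), gid), function(idx) {
    e <- flat[idx, , drop = FALSE]
    zs <- sort(unique(e$shared))
    data.frame(kind = e$kind[1], key_a = e$key_a[1], key_b = e$key_b[1],
               n_shared = length(zs), shared = paste(zs, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$kind, out$key_a, out$key_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
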