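## Pairwise abstraction.
##
## Every pair of distinct genes co-occurring in one (refined) event
## structure is a candidate association.  At the pair's lowest common
## ancestor event: both direct Themes of one binding event => binding
## (undirected); otherwise the Cause-side gene regulates the Theme-side
## gene.  Two qualifications follow the roles on the descent paths:
## a gene reached through a Theme role inside the Cause argument is only
## an indirect regulator (class indirect_regulation); and a gene that is
## a Cause inside the Theme argument makes the Cause–Cause candidate
## unclassifiable as a regulation — that pair is discarded as a direct
## association and kept only as a coregulation seed toward the inner
## event's Theme.

## Collect gene leaves of `root` with their descent paths.  Each leaf
## gets parallel vectors `events` (preorder index of each event on the
## path from the root) and `roles` (the argument role taken at that
## event), plus the leaf node itself.
collect_leaf_paths <- function(root) {
  nodes <- list()
  leaves <- list()
  walk <- function(node, ev_path, role_path) {
    if (!is_event_node(node)) {
      leaves[[length(leaves) + 1L]] <<-
        list(node = node, events = ev_path, roles = role_path)
      return(invisible(NULL))
    }
    nodes[[length(nodes) + 1L]] <<- node
    my_idx <- length(nodes)
    for (k in seq_along(node$children))
      walk(node$children[[k]], c(ev_path, my_idx), c(role_path, node$roles[k]))
  }
  walk(root, integer(0), character(0))
  list(nodes = nodes, leaves = leaves)
}

empty_pair_seeds <- function() {
  data.frame(key_a = character(0), key_b = character(0), cls = character(0),
             directed = logical(0), target = character(0),
             stringsAsFactors = FALSE)
}

#' Extract typed gene-pair seeds from one event structure
#'
#' Walks a (preferably refined) event structure and emits one seed per
#' unordered pair of distinct genes it relates: class `binding`
#' (undirected, keys in lexicographic order), `regulation` or
#' `indirect_regulation` (directed, `key_a` regulates `key_b`), or
#' `coregulation_capture` (undirected; a discarded Cause–Cause candidate
#' kept as a coregulation seed, with the shared target gene in
#' `target`).  Pairs whose two keys coincide are never emitted.
#'
#' @param root An event tree.
#' @param keys Optional named character vector mapping mention ids to
#'   generalization keys; leaves without an entry (or when `keys` is
#'   `NULL`) use their symbol.  Leaves mapping to `NA` are excluded.
#' @return A data.frame of seeds with columns `key_a`, `key_b`, `cls`,
#'   `directed`, `target`.
#' @export
extract_pairs <- function(root, keys = NULL) {
  if (inherits(root, "refined_event")) root <- root$structure
  cp <- collect_leaf_paths(root)
  leaves <- cp$leaves
  nodes <- cp$nodes
  if (length(leaves) < 2L) return(empty_pair_seeds())

  leaf_key <- function(leaf) {
    if (!is.null(keys) && !is.null(leaf$node$mention_id) &&
        leaf$node$mention_id %in% names(keys))
      return(unname(keys[leaf$node$mention_id]))
    leaf$node$symbol
  }
  lk <- vapply(leaves, leaf_key, character(1))

  acc <- list()
  add <- function(key_a, key_b, cls, directed, target = NA_character_) {
    acc[[length(acc) + 1L]] <<- c(key_a, key_b, cls,
                                  if (directed) "T" else "F", target)
  }

  n <- length(leaves)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ka <- lk[i]; kb <- lk[j]
    if (is.na(ka) || is.na(kb) || identical(ka, kb)) next
    pi <- leaves[[i]]; pj <- leaves[[j]]
    ## lowest common ancestor: deepest event shared by both descent
    ## paths (paths are root-to-leaf, so it is the longest common prefix)
    m <- min(length(pi$events), length(pj$events))
    cpl <- 0L
    while (cpl < m && pi$events[cpl + 1L] == pj$events[cpl + 1L])
      cpl <- cpl + 1L
    lca <- nodes[[pi$events[cpl]]]
    role_i <- pi$roles[cpl]; role_j <- pj$roles[cpl]

    if (lca$type == "binding") {
      k <- sort(c(ka, kb))
      add(k[1], k[2], "binding", FALSE)
      next
    }
    ## regulation-class LCA: exactly one of the two descends through the
    ## Cause argument (same role would imply the same child, i.e. a
    ## deeper common ancestor)
    if (role_i == role_j) next  # defensive; cannot happen on valid trees
    if (role_i == "Cause") { cause <- pi; ckey <- ka; theme <- pj; tkey <- kb }
    else                   { cause <- pj; ckey <- kb; theme <- pi; tkey <- ka }
    theme_suffix <- theme$roles[-seq_len(cpl)]
    cause_suffix <- cause$roles[-seq_len(cpl)]

    if (any(theme_suffix == "Cause")) {
      ## discarded Cause–Cause candidate: keep as coregulation seed
      ## toward the Theme of the deepest event where the theme-side
      ## gene acts as a Cause
      kpos <- max(which(theme$roles == "Cause"))
      inner <- nodes[[theme$events[kpos]]]
      targets <- unique(unlist(lapply(which(inner$roles == "Theme"), function(q)
        tree_gene_symbols(inner$children[[q]]))))
      if (!is.null(keys)) {
        tg <- lapply(which(inner$roles == "Theme"), function(q)
          tree_genes(inner$children[[q]]))
        targets <- unique(vapply(unlist(tg, recursive = FALSE), function(g) {
          if (!is.null(g$mention_id) && g$mention_id %in% names(keys))
            unname(keys[g$mention_id]) else g$symbol
        }, character(1)))
      }
      targets <- targets[!is.na(targets) & !targets %in% c(ckey, tkey)]
      k <- sort(c(ckey, tkey))
      if (length(targets) == 0L) add(k[1], k[2], "coregulation_capture", FALSE)
      else for (tg in sort(targets)) add(k[1], k[2], "coregulation_capture", FALSE, tg)
      next
    }
    cls <- if (any(cause_suffix == "Theme")) "indirect_regulation" else "regulation"
    add(ckey, tkey, cls, TRUE)
  }
  seeds_from_acc(acc)
}

## Assemble accumulated seed tuples into a deduplicated data.frame.
seeds_from_acc <- function(acc) {
  if (length(acc) == 0L) return(empty_pair_seeds())
  m <- do.call(rbind, acc)
  df <- data.frame(key_a = m[, 1], key_b = m[, 2], cls = m[, 3],
                   directed = m[, 4] == "T", target = m[, 5],
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Aggregate gene pairs across a corpus under a generalization scheme
#'
#' Extracts pair seeds from every refined root structure, keys genes by
#' the chosen generalization, and merges seeds on (keys, class,
#' direction), pooling evidence across documents.  The aggregate score
#' of a pair is the mean of its scored evidence; confidence categories
#' are assigned from the corpus-wide range of aggregate scores.
#'
#' @param corpus A refined (and ideally scored, canonicalized)
#'   `standoff_corpus`.
#' @param scheme `"canonical"` or a `family_scheme` (see
#'   [generalization_key()]).
#' @param bin_mode Binning mode for the confidence categories, see
#'   [confidence_bins()].
#' @return A `gene_pairs` object: list with `pairs` (one row per
#'   aggregated pair: `key_a`, `key_b`, `cls`, `directed`,
#'   `n_evidence`, `agg_score`, `category`, `best_doc`, `best_event`)
#'   and `evidence` (one row per supporting occurrence, with the shared
#'   `target` key for coregulation seeds).
#' @export
aggregate_pairs <- function(corpus, scheme = "canonical", bin_mode = "range") {
  ev_rows <- list()
  for (doc in corpus) {
    if (is.null(doc$refined))
      stop("corpus must be refined before pair aggregation; run refine_corpus()",
           call. = FALSE)
    if (nrow(doc$mentions) == 0L) next
    canon <- doc$mentions$canonical
    use <- !is.na(canon)
    keys <- structure(rep(NA_character_, nrow(doc$mentions)),
                      names = doc$mentions$mention_id)
    keys[use] <- generalization_key(canon[use], scheme)
    for (r in doc$refined) {
      seeds <- extract_pairs(r$structure, keys = keys)
      if (nrow(seeds) == 0L) next
      seeds$doc_id <- doc$doc_id
      seeds$event_id <- if (is.null(r$original_id)) NA_character_ else r$original_id
      seeds$score <- if (is.null(r$norm_score)) NA_real_ else r$norm_score
      ev_rows[[length(ev_rows) + 1L]] <- seeds
    }
  }
  evidence <- if (length(ev_rows)) do.call(rbind, ev_rows) else {
    ev <- empty_pair_seeds(); ev$doc_id <- character(0)
    ev$event_id <- character(0); ev$score <- numeric(0); ev
  }

  if (nrow(evidence) == 0L) {
    pairs <- data.frame(key_a = character(0), key_b = character(0),
                        cls = character(0), directed = logical(0),
                        n_evidence = integer(0), agg_score = numeric(0),
                        category = character(0), best_doc = character(0),
                        best_event = character(0), stringsAsFactors = FALSE)
    return(structure(list(pairs = pairs, evidence = evidence,
                          scheme = scheme_name(scheme), bins = NULL),
                     class = "gene_pairs"))
  }

  gid <- paste(evidence$key_a, evidence$key_b, evidence$cls, evidence$directed,
               sep = "\r")
  groups <- split(seq_len(nrow(evidence)), gid)
  pairs <- do.call(rbind, lapply(groups, function(idx) {
    e <- evidence[idx, , drop = FALSE]
    agg <- score_generalized(e$score)
    best <- if (all(is.na(e$score))) 1L else which.max(e$score)
    data.frame(key_a = e$key_a[1], key_b = e$key_b[1], cls = e$cls[1],
               directed = e$directed[1], n_evidence = nrow(e),
               agg_score = agg, best_doc = e$doc_id[best],
               best_event = e$event_id[best], stringsAsFactors = FALSE)
  }))
  pairs <- pairs[order(pairs$cls, pairs$key_a, pairs$key_b), , drop = FALSE]
  rownames(pairs) <- NULL

  bins <- NULL
  if (any(!is.na(pairs$agg_score))) {
    bins <- confidence_bins(pairs$agg_score, mode = bin_mode)
    pairs$category <- as.character(categorize(pairs$agg_score, bins))
  } else {
    pairs$category <- NA_character_
  }
  structure(list(pairs = pairs, evidence = evidence,
                 scheme = scheme_name(scheme), bins = bins),
            class = "gene_pairs")
}

scheme_name <- function(scheme) {
  if (identical(scheme, "canonical")) "canonical" else scheme$name
}

#' @export
print.gene_pairs <- function(x, ...) {
  cat(sprintf("<gene_pairs (%s scheme): %d pairs, %d evidence rows>\n",
              x$scheme, nrow(x$pairs), nrow(x$evidence)))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10))
  invisible(x)
}

#' Filter aggregated pairs by a confidence threshold
#'
#' Keeps pairs whose aggregate score is at least `min_score` (unscored
#' pairs are dropped), implementing the precision/recall trade-off
#' screening.
#'
#' @param gp A `gene_pairs` object.
#' @param min_score Numeric threshold.
#' @return A filtered `gene_pairs` object.
#' @export
filter_pairs <- function(gp, min_score) {
  keep <- !is.na(gp$pairs$agg_score) & gp$pairs$agg_score >= min_score
  gp$pairs <- gp$pairs[keep, , drop = FALSE]
  rownames(gp$pairs) <- NULL
  gp
}

#' Threshold sweep over aggregate pair scores
#'
#' Sweeps a confidence cut-off over the observed score range with a
#' fixed step and reports, per threshold, how many pairs survive; when
#' a reference pair set is supplied (data.frame with `key_a`, `key_b`,
#' `cls`), precision and recall against it are reported as well.
#'
#' @param gp A `gene_pairs` object.
#' @param step Threshold step size (default 0.05).
#' @param reference Optional reference pair table.
#' @return A data.frame with columns `threshold`, `n_kept` and, given a
#'   reference, `precision`, `recall`.
#' @export
threshold_sweep <- function(gp, step = 0.05, reference = NULL) {
  sc <- gp$pairs$agg_score
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L)
    return(data.frame(threshold = numeric(0), n_kept = integer(0)))
  thresholds <- seq(floor(min(sc) / step) * step,
                    ceiling(max(sc) / step) * step, by = step)
  pair_id <- function(df) paste(df$key_a, df$key_b, df$cls, sep = "\r")
  ref_ids <- if (!is.null(reference)) unique(pair_id(reference)) else NULL
  rows <- lapply(thresholds, function(t) {
    kept <- gp$pairs[!is.na(gp$pairs$agg_score) & gp$pairs$agg_score >= t, ,
                     drop = FALSE]
    out <- data.frame(threshold = t, n_kept = nrow(kept))
    if (!is.null(ref_ids)) {
      ids <- unique(pair_id(kept))
      tp <- sum(ids %in% ref_ids)
      out$precision <- if (length(ids)) tp / length(ids) else NA_real_
      out$recall <- if (length(ref_ids)) tp / length(ref_ids) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}
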