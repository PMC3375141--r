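# Fixtures built in code: a small hand-written document in the standoff
# dialect, plus helpers used across the suite.

# "IL-2 enhances binding of NF-kB to p55": a positive regulation whose
# Theme is a binding event and whose Cause is a gene mention.
fixture_text <- "IL-2 enhances binding of NF-kB to p55"

fixture_entity_lines <- c(
  "T1\tProtein 0 4\tIL-2",
  "T2\tProtein 25 30\tNF-kB",
  "T3\tProtein 34 37\tp55"
)

fixture_event_lines <- c(
  "T4\tPositive_regulation 5 13\tenhances",
  "T5\tBinding 14 21\tbinding",
  "E1\tPositive_regulation:T4 Cause:T1 Theme:E2",
  "E2\tBinding:T5 Theme:T2 Theme:T3"
)

fixture_document <- function() {
  read_standoff(fixture_entity_lines, fixture_event_lines, fixture_text,
                doc_id = "fix01")
}

# Build a one-structure document directly from a bracket string, laying
# out tokens "trigger gene trigger gene ..." with correct offsets.
doc_from_bracket <- function(s, doc_id = "b01") {
  tree <- parse_bracket(s)
  trig_words <- list(
    gene_expression = "expressed", transcription = "transcribed",
    localization = "localized", protein_catabolism = "degraded",
    phosphorylation = "phosphorylated", binding = "binds",
    regulation = "regulates", positive_regulation = "activates",
    negative_regulation = "inhibits")
  tokens <- character(0)
  mention_rows <- list()
  trigger_lines <- character(0)
  event_lines <- character(0)
  counters <- new.env(parent = emptyenv())
  counters$m <- 0L; counters$t <- 0L; counters$e <- 0L; counters$pos <- 0L

  push <- function(txt) {
    start <- counters$pos + if (length(tokens)) 1L else 0L
    counters$pos <- start + nchar(txt)
    tokens <<- c(tokens, txt)
    start
  }
  # count mentions first so trigger ids can follow the entity namespace
  n_mentions <- length(tree_gene_symbols_pub(tree))
  emit <- function(node) {
    if (node$kind == "gene") {
      counters$m <- counters$m + 1L
      id <- paste0("T", counters$m)
      start <- push(node$symbol)
      mention_rows[[length(mention_rows) + 1L]] <<-
        sprintf("%s\tProtein %d %d\t%s", id, start, start + nchar(node$symbol),
                node$symbol)
      return(id)
    }
    word <- trig_words[[node$type]]
    start <- push(word)
    counters$t <- counters$t + 1L
    tid <- paste0("T", n_mentions + counters$t)
    trigger_lines <<- c(trigger_lines,
                        sprintf("%s\t%s %d %d\t%s", tid, st_name(node$type),
                                start, start + nchar(word), word))
    targets <- vapply(node$children, emit, character(1))
    counters$e <- counters$e + 1L
    eid <- paste0("E", counters$e)
    event_lines <<- c(event_lines,
                      sprintf("%s\t%s:%s %s", eid, st_name(node$type), tid,
                              paste(paste0(node$roles, ":", targets),
                                    collapse = " ")))
    eid
  }
  emit(tree)
  text <- paste(tokens, collapse = " ")
  read_standoff(unlist(mention_rows), c(trigger_lines, event_lines), text,
                doc_id = doc_id)
}

st_name <- function(type) paste0(toupper(substring(type, 1, 1)), substring(type, 2))

tree_gene_symbols_pub <- function(node) {
  if (node$kind == "gene") return(node$symbol)
  unlist(lapply(node$children, tree_gene_symbols_pub))
}

# Canonical comparison form for pair seed tables.
seed_key <- function(df) {
  sort(paste(df$key_a, df$key_b, df$cls, df$directed,
             ifelse(is.na(df$target), "-", df$target)))
}

# Random regulation chain/tree generator for property tests.
random_reg_tree <- function(max_depth = 5, p_cause = 0.4, genes = letters[1:6]) {
  build <- function(depth) {
    if (depth <= 0 || runif(1) < 0.25) return(ev_gene(sample(genes, 1)))
    type <- sample(c("regulation", "positive_regulation", "negative_regulation",
                     "phosphorylation", "binding"), 1,
                   prob = c(0.25, 0.25, 0.25, 0.15, 0.1))
    if (type == "phosphorylation") {
      ev_event(type, "Theme", list(ev_gene(sample(genes, 1))))
    } else if (type == "binding") {
      k <- sample(2:3, 1)
      ev_event(type, rep("Theme", k),
               lapply(sample(genes, k), ev_gene))
    } else {
      roles <- "Theme"
      children <- list(build(depth - 1L))
      if (runif(1) < p_cause) {
        roles <- c("Cause", roles)
        children <- c(list(build(depth - 1L)), children)
      }
      ev_event(type, roles, children)
    }
  }
  build(max_depth)
}

# Does the tree contain a removable redex (regulation whose Theme is a
# Cause-less regulation)?  Used for the fixpoint characterization.
has_redex <- function(node) {
  if (node$kind != "event") return(FALSE)
  if (node$type %in% c("regulation", "positive_regulation", "negative_regulation")) {
    ti <- which(node$roles == "Theme")
    if (length(ti) == 1L) {
      th <- node$children[[ti]]
      if (th$kind == "event" &&
          th$type %in% c("regulation", "positive_regulation", "negative_regulation") &&
          !any(th$roles == "Cause"))
        return(TRUE)
    }
  }
  any(vapply(node$children, has_redex, logical(1)))
}

# Root events: events not referenced as an argument of another event.
root_event_ids_pub <- function(doc) {
  used <- unlist(lapply(doc$events, function(ev) ev$targets), use.names = FALSE)
  setdiff(names(doc$events), used)
}
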