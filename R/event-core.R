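## In-memory resolved event trees.
##
## A node is a plain list with $kind either "gene" (a leaf mention) or
## "event".  Event nodes hold parallel vectors $roles ("Theme"/"Cause")
## and $children (list of nodes).  Plain lists keep traversal cheap; the
## "ev_node" class is only used for printing.

#' Construct a gene leaf node
#'
#' @param symbol Gene symbol (surface or generalization key).
#' @param mention_id Optional annotation id of the underlying mention.
#' @return An event-tree leaf node.
#' @export
ev_gene <- function(symbol, mention_id = NULL) {
  structure(list(kind = "gene", symbol = symbol, mention_id = mention_id),
            class = "ev_node")
}

#' Construct an event node
#'
#' @param type Internal event type name (see [is_regulation_type()]).
#' @param roles Character vector of argument roles, "Theme" or "Cause".
#' @param children List of child nodes (gene leaves or events), parallel
#'   to `roles`.
#' @param event_id,trigger Optional annotation id and trigger word.
#' @return An event-tree node.
#' @export
ev_event <- function(type, roles, children, event_id = NULL, trigger = NULL) {
  stopifnot(type %in% EVENT_TYPES, length(roles) == length(children))
  structure(list(kind = "event", type = type, roles = as.character(roles),
                 children = children, event_id = event_id, trigger = trigger),
            class = "ev_node")
}

is_event_node <- function(node) identical(node$kind, "event")

#' Parse the bracketed event notation
#'
#' Parses strings such as
#' `"Positive-Regulation(C:IL-2, T:Binding(T:NF-kB, T:p55))"` into an
#' event tree.  Type names are matched case-insensitively, with `-`, `_`
#' and spaces interchangeable; the shorthands `Pos`, `Neg`, `Reg`,
#' `Bind` and `Phos` are accepted.  Roles are `T:` (Theme) and `C:`
#' (Cause).
#'
#' @param s A single bracket-notation string.
#' @return An event tree (see [ev_event()]); a bare symbol parses to a
#'   gene leaf.
#' @seealso [print_bracket()] for the inverse.
#' @export
parse_bracket <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pos <- 1L
  n <- length(chars)

  fail <- function(msg, at = pos) {
    stop(sprintf("bracket parse error at position %d: %s", at, msg), call. = FALSE)
  }
  skip_ws <- function() {
    while (pos <= n && chars[pos] %in% c(" ", "\t")) pos <<- pos + 1L
  }
  read_token <- function() {
    start <- pos
    while (pos <= n && !chars[pos] %in% c("(", ")", ",", ":")) pos <<- pos + 1L
    trimws(paste(chars[start:(pos - 1L)], collapse = ""))
  }

  parse_node <- function() {
    skip_ws()
    if (pos > n) fail("unexpected end of input")
    start_at <- pos
    tok <- read_token()
    if (!nzchar(tok)) fail("empty token", start_at)
    skip_ws()
    if (pos <= n && chars[pos] == "(") {
      type <- normalize_type_name(tok)
      if (is.na(type)) fail(sprintf("unknown event type '%s'", tok), start_at)
      pos <<- pos + 1L  # consume "("
      roles <- character(0)
      children <- list()
      repeat {
        skip_ws()
        if (pos > n) fail("unbalanced parentheses: missing ')'")
        role_at <- pos
        role_tok <- read_token()
        skip_ws()
        if (pos > n || chars[pos] != ":")
          fail("expected ':' after argument role", pos)
        role <- switch(toupper(role_tok),
                       "T" = "Theme", "THEME" = "Theme",
                       "C" = "Cause", "CAUSE" = "Cause",
                       fail(sprintf("unknown role '%s'", role_tok), role_at))
        pos <<- pos + 1L  # consume ":"
        child <- parse_node()
        roles <- c(roles, role)
        children <- c(children, list(child))
        skip_ws()
        if (pos > n) fail("unbalanced parentheses: missing ')'")
        if (chars[pos] == ",") { pos <<- pos + 1L; next }
        if (chars[pos] == ")") { pos <<- pos + 1L; break }
        fail(sprintf("expected ',' or ')', got '%s'", chars[pos]))
      }
      ev_event(type, roles, children)
    } else {
      ev_gene(tok)
    }
  }

  node <- parse_node()
  skip_ws()
  if (pos <= n) fail("trailing input after event")
  node
}

#' Print an event tree in bracketed notation
#'
#' Inverse of [parse_bracket()] under canonical spacing: arguments are
#' separated by `", "`, roles abbreviated to `C:`/`T:`, and type names
#' printed in hyphenated form (`Positive-Regulation`).
#'
#' @param node An event tree node.
#' @return A single string.
#' @export
print_bracket <- function(node) {
  if (!is_event_node(node)) return(node$symbol)
  args <- mapply(function(role, child) {
    paste0(substring(role, 1, 1), ":", print_bracket(child))
  }, node$roles, node$children)
  paste0(bracket_type_name(node$type), "(", paste(args, collapse = ", "), ")")
}

#' @export
format.ev_node <- function(x, ...) print_bracket(x)

#' @export
print.ev_node <- function(x, ...) {
  cat(print_bracket(x), "\n")
  invisible(x)
}

## Order argument indices for deterministic traversal: Cause before Theme,
## preserving the original order within each role.
ordered_args <- function(node) {
  order(match(node$roles, c("Cause", "Theme")))
}

#' Structural signature of an event tree
#'
#' Collapses an event structure to its coarse pattern: regulation-class
#' types become `*Reg`, binding stays `Bind`, single-Theme physical types
#' become `Phy`, and genes are replaced by placeholder letters `A`, `B`,
#' ... assigned in traversal order (Cause arguments before Theme
#' arguments at each level).  Two structurally isomorphic events —
#' regardless of annotation ids, trigger words, polarity or concrete
#' physical type — yield the same signature string.
#'
#' @param node An event tree node.
#' @return A single signature string, e.g. `"*Reg(C:A, T:Phy(T:B))"`.
#' @export
event_signature <- function(node) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  sig <- function(nd) {
    if (!is_event_node(nd)) {
      counter$i <- counter$i + 1L
      if (counter$i > 26L) return(paste0("G", counter$i))
      return(LETTERS[counter$i])
    }
    head <- if (is_regulation_type(nd$type)) "*Reg"
            else if (nd$type == "binding") "Bind"
            else "Phy"
    idx <- ordered_args(nd)
    args <- vapply(idx, function(i) {
      paste0(substring(nd$roles[i], 1, 1), ":", sig(nd$children[[i]]))
    }, character(1))
    paste0(head, "(", paste(args, collapse = ", "), ")")
  }
  sig(node)
}

#' Tabulate event-structure signatures over a corpus
#'
#' Counts the structural signature of every root event structure and
#' reports occurrence percentages and cumulative percentages, most
#' frequent first (ties broken lexicographically for determinism).
#'
#' @param trees A list of event trees, or a `standoff_corpus` (in which
#'   case refined structures are used when present, raw root events
#'   otherwise).
#' @param top_n Optionally keep only the `top_n` most frequent rows and
#'   collapse the remainder into a final `"(other)"` row, so that
#'   percentages still sum to 100.
#' @return A data.frame with columns `signature`, `count`, `pct`,
#'   `cum_pct`.
#' @export
count_signatures <- function(trees, top_n = NULL) {
  if (inherits(trees, "standoff_corpus")) trees <- corpus_trees(trees)
  if (length(trees) == 0L) {
    return(data.frame(signature = character(0), count = integer(0),
                      pct = numeric(0), cum_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sigs <- vapply(trees, event_signature, character(1))
  tab <- table(sigs)
  df <- data.frame(signature = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$signature), , drop = FALSE]
  if (!is.null(top_n) && nrow(df) > top_n) {
    rest <- df[-seq_len(top_n), , drop = FALSE]
    df <- df[seq_len(top_n), , drop = FALSE]
    df <- rbind(df, data.frame(signature = "(other)",
                               count = sum(rest$count),
                               stringsAsFactors = FALSE))
  }
  df$pct <- 100 * df$count / sum(df$count)
  df$cum_pct <- cumsum(df$pct)
  rownames(df) <- NULL
  df
}

## All gene leaves of a tree, in traversal order (stored argument order).
tree_genes <- function(node) {
  if (!is_event_node(node)) return(list(node))
  out <- list()
  for (child in node$children) out <- c(out, tree_genes(child))
  out
}

## Multiset of gene symbols in a tree.
tree_gene_symbols <- function(node) {
  vapply(tree_genes(node), function(g) g$symbol, character(1))
}

## Count of event nodes in a tree.
tree_event_count <- function(node) {
  if (!is_event_node(node)) return(0L)
  1L + sum(vapply(node$children, tree_event_count, integer(1)))
}

## Nesting depth in events (a leaf has depth 0).
tree_depth <- function(node) {
  if (!is_event_node(node)) return(0L)
  1L + max(c(0L, vapply(node$children, tree_depth, integer(1))))
}
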