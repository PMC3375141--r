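## Event refinement.
##
## Event extraction follows sentence wording closely, so statements such
## as "Ang II induces a rapid increase in MAPK activity" come out as
## Positive-Regulation(C:AngII, T:Positive-Regulation(T:MAPK)) — a chain
## of nested regulations where one would do.  The rewrite system removes
## intermediary single-argument regulatory events (regulation-class
## events with a Theme but no Cause) and composes the polarities of the
## outer and nested event.  Because removing a mixed-polarity chain can
## flip the outer event's polarity, and each flip is an inference not
## literally present in the sentence, only one polarity change is
## allowed per event structure; any later type-changing application is
## forced to unspecified regulation.

## Short polarity codes for the rule table.
POLARITY_CODE <- c(positive_regulation = "Pos",
                   negative_regulation = "Neg",
                   regulation = "Reg")
POLARITY_TYPE <- structure(names(POLARITY_CODE), names = POLARITY_CODE)

## The nine-rule composition table: result polarity of removing a nested
## Cause-less regulation of polarity `nested` under an outer event of
## polarity `outer`.  Unspecified composes as the identity except that
## an informative nested polarity wins; two negatives make a positive.
POLARITY_RULES <- matrix(
  c(# nested: Pos    Reg    Neg        outer:
        "Pos", "Pos", "Neg",         # Pos
        "Pos", "Reg", "Neg",         # Reg
        "Neg", "Neg", "Pos"),        # Neg
  nrow = 3, byrow = TRUE,
  dimnames = list(outer = c("Pos", "Reg", "Neg"),
                  nested = c("Pos", "Reg", "Neg")))

#' Compose the polarity of an outer and a nested regulation
#'
#' Implements the nine-rule polarity table of the rewrite system, e.g.
#' a negative regulation of a negative regulation composes to a
#' positive regulation ("E2 prevented downregulation of p21").
#'
#' @param outer,nested Internal regulation-class type names (or the
#'   short codes `"Pos"`, `"Neg"`, `"Reg"`).
#' @return A list with `result` (internal type name) and
#'   `is_type_change` (`TRUE` iff the result differs from the outer
#'   type).
#' @export
compose_polarity <- function(outer, nested) {
  to_code <- function(x) {
    if (x %in% names(POLARITY_CODE)) return(unname(POLARITY_CODE[x]))
    if (x %in% rownames(POLARITY_RULES)) return(x)
    stop(sprintf("'%s' is not a regulation-class type", x), call. = FALSE)
  }
  oc <- to_code(outer); nc <- to_code(nested)
  rc <- POLARITY_RULES[oc, nc]
  list(result = unname(POLARITY_TYPE[rc]), is_type_change = rc != oc)
}

## Is this node a removable nested unit: a regulation-class event with a
## Theme and no Cause argument?
is_causeless_regulation <- function(node) {
  is_event_node(node) && is_regulation_type(node$type) &&
    !any(node$roles == "Cause")
}

#' Refine an event structure
#'
#' Iteratively removes intermediary single-argument regulatory events,
#' outermost first with re-scan from the root: wherever a
#' regulation-class event's Theme is itself a Cause-less
#' regulation-class event, the nested event is spliced out, the outer
#' event inherits its Theme, and the outer type is set by
#' [compose_polarity()].  After the first polarity-changing application
#' anywhere in the structure, every subsequent type-changing application
#' forces the outer type to unspecified regulation.  Non-regulation
#' events and nested regulations carrying a Cause are untouched, so the
#' gene content of the structure is preserved exactly.
#'
#' @param root An event tree (see [resolve_event()], [parse_bracket()]).
#' @return A `refined_event`: list with `structure` (the rewritten
#'   tree), `original` (the untouched input tree), `original_id`,
#'   `polarity_changes_used` (0 or 1), `forced_unspecified`, and
#'   `removed_triggers` (trigger provenance of spliced-out events).
#' @export
refine_event <- function(root) {
  state <- new.env(parent = emptyenv())
  state$changes <- 0L
  state$forced <- FALSE
  state$removed <- list()

  collapse <- function(node) {
    if (!is_event_node(node)) return(node)
    if (is_regulation_type(node$type)) {
      repeat {
        ti <- which(node$roles == "Theme")
        if (length(ti) != 1L || !is_causeless_regulation(node$children[[ti]]))
          break
        nested <- node$children[[ti]]
        nti <- which(nested$roles == "Theme")
        comp <- compose_polarity(node$type, nested$type)
        if (comp$is_type_change) {
          if (state$changes >= 1L) {
            node$type <- "regulation"
            state$forced <- TRUE
          } else {
            node$type <- comp$result
            state$changes <- state$changes + 1L
          }
        } else {
          node$type <- comp$result
        }
        state$removed <- c(state$removed,
                           list(list(event_id = nested$event_id,
                                     type = nested$type,
                                     trigger = nested$trigger)))
        node$children[[ti]] <- nested$children[[nti]]
      }
    }
    node$children <- lapply(node$children, collapse)
    node
  }

  structure(list(structure = collapse(root),
                 original = root,
                 original_id = root$event_id,
                 polarity_changes_used = state$changes,
                 forced_unspecified = state$forced,
                 removed_triggers = state$removed),
            class = "refined_event")
}

#' @export
print.refined_event <- function(x, ...) {
  cat(sprintf("<refined_event: %s  (from %s; %d polarity change%s%s)>\n",
              print_bracket(x$structure), print_bracket(x$original),
              x$polarity_changes_used,
              if (x$polarity_changes_used == 1L) "" else "s",
              if (x$forced_unspecified) ", forced unspecified" else ""))
  invisible(x)
}

#' Refine every root event structure of a corpus
#'
#' Resolves each document's root events (events not serving as an
#' argument of another event) into trees and refines them; the refined
#' structures are stored on each document as `$refined`, originals
#' preserved.  Occurrence scores, when present, are inherited by the
#' refined structures.
#'
#' @param corpus A `standoff_corpus`.
#' @return The corpus with refined structures attached.
#' @export
refine_corpus <- function(corpus) {
  for (i in seq_along(corpus)) {
    doc <- corpus[[i]]
    refined <- lapply(root_event_ids(doc), function(eid) {
      r <- refine_event(resolve_event(doc, eid))
      r$doc_id <- doc$doc_id
      r$norm_score <- doc$events[[eid]]$norm_score
      r
    })
    corpus[[i]]$refined <- refined
  }
  corpus
}
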