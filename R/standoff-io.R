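## Standoff annotation IO.
##
## A document is text plus two standoff annotation streams: an entity
## stream (gene/protein mentions, one per line, "Tn<TAB>TYPE start
## end<TAB>surface") and an event stream (trigger lines in the same
## shape plus event lines "En<TAB>TYPE:Tk Role:Target ...").  Offsets
## are 0-based, end-exclusive, in characters.  An optional confidence
## sidecar carries raw classifier margins for triggers and arguments.

new_document <- function(doc_id, text, mentions, events) {
  structure(list(doc_id = doc_id, text = text,
                 mentions = mentions, events = events),
            class = "standoff_document")
}

empty_mentions <- function() {
  data.frame(mention_id = character(0), start = integer(0), end = integer(0),
             surface = character(0), canonical = character(0),
             stringsAsFactors = FALSE)
}

text_slice <- function(text, start, end) substr(text, start + 1L, end)

split_fields <- function(line) strsplit(line, "\t", fixed = TRUE)[[1]]

parse_span_line <- function(line, lineno, stream) {
  f <- split_fields(line)
  if (length(f) != 3L)
    stop(sprintf("%s line %d: expected 3 tab-separated fields, got %d",
                 stream, lineno, length(f)), call. = FALSE)
  mid <- strsplit(f[2], " ", fixed = TRUE)[[1]]
  if (length(mid) != 3L || anyNA(suppressWarnings(as.integer(mid[2:3]))))
    stop(sprintf("%s line %d: expected 'TYPE start end', got '%s'",
                 stream, lineno, f[2]), call. = FALSE)
  list(id = f[1], type = mid[1],
       start = as.integer(mid[2]), end = as.integer(mid[3]),
       surface = f[3])
}

as_lines <- function(x) {
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x[nzchar(trimws(x))]
}

#' Read a standoff-annotated document
#'
#' Parses an entity stream and an event stream against the document
#' text, resolving all references, and validates the event-model
#' argument constraints (see [validate_event_constraints()]).
#'
#' @param entity_lines Character vector (or single newline-joined
#'   string) of entity lines `"Tn<TAB>TYPE start end<TAB>surface"`.
#' @param event_lines Character vector of trigger lines (same shape) and
#'   event lines `"En<TAB>TYPE:Tk Role:Target ..."`; roles are `Theme`
#'   (numbered variants `Theme2`, ... accepted) and `Cause`.
#' @param text Document text; offsets are 0-based, end-exclusive
#'   character positions into it.
#' @param doc_id Document identifier.
#' @param validate If `TRUE` (default), reject documents violating the
#'   event-model constraints.
#' @return A `standoff_document`.
#' @export
read_standoff <- function(entity_lines, event_lines, text, doc_id = "doc",
                          validate = TRUE) {
  entity_lines <- as_lines(entity_lines)
  event_lines <- as_lines(event_lines)

  mentions <- empty_mentions()
  for (i in seq_along(entity_lines)) {
    p <- parse_span_line(entity_lines[i], i, "entity stream")
    if (p$start < 0L || p$start >= p$end || p$end > nchar(text))
      stop(sprintf("entity stream line %d: offsets [%d,%d) outside text of length %d",
                   i, p$start, p$end, nchar(text)), call. = FALSE)
    slice <- text_slice(text, p$start, p$end)
    if (!identical(slice, p$surface))
      stop(sprintf("entity stream line %d: surface '%s' does not match text slice '%s'",
                   i, p$surface, slice), call. = FALSE)
    mentions <- rbind(mentions, data.frame(
      mention_id = p$id, start = p$start, end = p$end,
      surface = p$surface, canonical = NA_character_,
      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(mentions$mention_id))
    stop("entity stream: duplicate annotation ids", call. = FALSE)

  triggers <- list()
  events <- list()
  for (i in seq_along(event_lines)) {
    line <- event_lines[i]
    id0 <- substring(line, 1, 1)
    if (id0 == "T") {
      p <- parse_span_line(line, i, "event stream")
      if (p$start < 0L || p$start >= p$end || p$end > nchar(text))
        stop(sprintf("event stream line %d: trigger offsets outside text", i),
             call. = FALSE)
      if (!identical(text_slice(text, p$start, p$end), p$surface))
        stop(sprintf("event stream line %d: trigger text does not match text slice", i),
             call. = FALSE)
      type <- normalize_type_name(p$type)
      if (is.na(type))
        stop(sprintf("event stream line %d: unknown event type '%s'", i, p$type),
             call. = FALSE)
      triggers[[p$id]] <- list(type = type, start = p$start, end = p$end,
                               text = p$surface)
    } else if (id0 == "E") {
      f <- split_fields(line)
      if (length(f) != 2L)
        stop(sprintf("event stream line %d: expected 2 tab-separated fields", i),
             call. = FALSE)
      toks <- strsplit(f[2], " +")[[1]]
      head <- strsplit(toks[1], ":", fixed = TRUE)[[1]]
      if (length(head) != 2L)
        stop(sprintf("event stream line %d: malformed event head '%s'", i, toks[1]),
             call. = FALSE)
      type <- normalize_type_name(head[1])
      if (is.na(type))
        stop(sprintf("event stream line %d: unknown event type '%s'", i, head[1]),
             call. = FALSE)
      roles <- character(0); targets <- character(0)
      for (tok in toks[-1]) {
        rt <- strsplit(tok, ":", fixed = TRUE)[[1]]
        if (length(rt) != 2L)
          stop(sprintf("event stream line %d: malformed argument '%s'", i, tok),
               call. = FALSE)
        role <- sub("[0-9]+$", "", rt[1])
        if (!role %in% c("Theme", "Cause"))
          stop(sprintf("event stream line %d: unknown role '%s'", i, rt[1]),
               call. = FALSE)
        roles <- c(roles, role); targets <- c(targets, rt[2])
      }
      events[[f[1]]] <- list(event_id = f[1], type = type,
                             trigger_ref = head[2],
                             trigger_start = NA_integer_, trigger_end = NA_integer_,
                             trigger_text = NA_character_,
                             roles = roles, targets = targets,
                             trigger_score = NA_real_,
                             arg_scores = rep(NA_real_, length(roles)),
                             norm_score = NA_real_)
    } else {
      stop(sprintf("event stream line %d: unknown annotation id '%s'",
                   i, split_fields(line)[1]), call. = FALSE)
    }
  }

  for (eid in names(events)) {
    ev <- events[[eid]]
    trg <- triggers[[ev$trigger_ref]]
    if (is.null(trg))
      stop(sprintf("integrity error: event %s references unknown trigger %s",
                   eid, ev$trigger_ref), call. = FALSE)
    if (!identical(trg$type, ev$type))
      stop(sprintf("integrity error: event %s type differs from its trigger's type",
                   eid), call. = FALSE)
    ev$trigger_start <- trg$start; ev$trigger_end <- trg$end
    ev$trigger_text <- trg$text
    ev$trigger_ref <- NULL
    events[[eid]] <- ev
  }

  doc <- new_document(doc_id, text, mentions, events)
  if (validate) {
    viol <- validate_event_constraints(doc)
    if (nrow(viol) > 0L)
      stop(sprintf("validation error in document '%s': %s", doc_id,
                   paste(sprintf("%s [%s] %s", viol$event_id, viol$rule,
                                 viol$message), collapse = "; ")),
           call. = FALSE)
  }
  doc
}

#' Validate the event-model argument constraints of a document
#'
#' Checks every event against the event model: (1) the five single-Theme
#' physical types carry exactly one argument, a Theme, targeting a gene
#' mention; (2) binding events have one or more Theme arguments, all
#' gene mentions, and no Cause; (3) regulation-class events have exactly
#' one Theme and at most one Cause, each a mention or an event.  Also
#' reports dangling argument references and cycles in the argument
#' graph.  Violations are returned as data, not raised.
#'
#' @param doc A `standoff_document`.
#' @return A data.frame with columns `event_id`, `rule`, `message`;
#'   zero rows iff the document satisfies all constraints.
#' @export
validate_event_constraints <- function(doc) {
  out <- data.frame(event_id = character(0), rule = character(0),
                    message = character(0), stringsAsFactors = FALSE)
  add <- function(eid, rule, msg) {
    out <<- rbind(out, data.frame(event_id = eid, rule = rule, message = msg,
                                  stringsAsFactors = FALSE))
  }
  mention_ids <- doc$mentions$mention_id
  event_ids <- names(doc$events)

  for (eid in event_ids) {
    ev <- doc$events[[eid]]
    is_mention <- ev$targets %in% mention_ids
    is_event <- ev$targets %in% event_ids
    if (any(!is_mention & !is_event)) {
      add(eid, "dangling-ref",
          sprintf("unresolved argument target(s): %s",
                  paste(ev$targets[!is_mention & !is_event], collapse = ", ")))
      next
    }
    n_theme <- sum(ev$roles == "Theme")
    n_cause <- sum(ev$roles == "Cause")
    if (is_physical_type(ev$type)) {
      if (length(ev$roles) != 1L || n_theme != 1L || !is_mention[1])
        add(eid, "single-theme-type",
            sprintf("%s must have exactly one Theme argument, a gene mention",
                    ev$type))
    } else if (ev$type == "binding") {
      if (n_cause > 0L)
        add(eid, "binding-no-cause", "binding events cannot have a Cause argument")
      if (n_theme < 1L || any(ev$roles == "Theme" & !is_mention))
        add(eid, "binding-theme-mention",
            "binding events need >= 1 Theme arguments, all gene mentions")
    } else {
      if (n_theme != 1L || n_cause > 1L || n_theme + n_cause != length(ev$roles))
        add(eid, "regulation-args",
            "regulation-class events must have exactly one Theme and at most one Cause")
    }
  }

  ## acyclicity of the argument graph (event -> event edges)
  state <- new.env(parent = emptyenv())
  for (eid in event_ids) state[[eid]] <- 0L  # 0 unseen, 1 open, 2 done
  visit <- function(eid) {
    if (state[[eid]] == 1L) return(TRUE)   # cycle
    if (state[[eid]] == 2L) return(FALSE)
    state[[eid]] <- 1L
    cyc <- FALSE
    for (t in doc$events[[eid]]$targets)
      if (t %in% event_ids && visit(t)) cyc <- TRUE
    state[[eid]] <- 2L
    cyc
  }
  for (eid in event_ids)
    if (state[[eid]] == 0L && visit(eid))
      add(eid, "acyclic", "argument graph contains a cycle through this event")

  out
}

#' Write a document back to standoff streams
#'
#' Annotation ids are renumbered (`T1..` mentions, then triggers, `E1..`
#' events) so the round trip [read_standoff()] of the result reproduces
#' the document up to id renaming.
#'
#' @param doc A `standoff_document`.
#' @return A list with character vectors `entity_lines` and
#'   `event_lines`, plus the id renumbering maps `mention_map` and
#'   `event_map` (old id -> emitted id).
#' @export
write_standoff <- function(doc) {
  m <- doc$mentions
  mention_map <- structure(paste0("T", seq_len(nrow(m))), names = m$mention_id)
  entity_lines <- sprintf("%s\tProtein %d %d\t%s",
                          mention_map[m$mention_id], m$start, m$end, m$surface)

  eids <- names(doc$events)
  event_map <- structure(paste0("E", seq_along(eids)), names = eids)
  trig_i <- nrow(m)
  event_lines <- character(0)
  for (k in seq_along(eids)) {
    ev <- doc$events[[eids[k]]]
    trig_i <- trig_i + 1L
    tid <- paste0("T", trig_i)
    event_lines <- c(event_lines,
                     sprintf("%s\t%s %d %d\t%s", tid, st_type_name(ev$type),
                             ev$trigger_start, ev$trigger_end, ev$trigger_text))
    tgt <- ifelse(ev$targets %in% names(mention_map),
                  mention_map[ev$targets], event_map[ev$targets])
    args <- paste(paste0(ev$roles, ":", tgt), collapse = " ")
    event_lines <- c(event_lines,
                     sprintf("%s\t%s:%s%s", event_map[eids[k]],
                             st_type_name(ev$type), tid,
                             if (nzchar(args)) paste0(" ", args) else ""))
  }
  list(entity_lines = entity_lines, event_lines = event_lines,
       mention_map = mention_map, event_map = event_map)
}

#' Attach raw classifier margins from a confidence sidecar
#'
#' The sidecar is a TSV with columns `doc_id`, `annotation_ref`, `kind`
#' (`trigger` or `argument`) and `score`.  Trigger rows reference
#' `"E1#trigger"`, argument rows `"E1#0"` (0-based argument index).
#' Events without sidecar rows keep their score fields unset.
#'
#' @param lines Character vector (or newline-joined string) of sidecar
#'   rows; rows for other documents are ignored.
#' @param doc A `standoff_document`.
#' @return The document with `trigger_score` / `arg_scores` filled.
#' @export
read_confidence_sidecar <- function(lines, doc) {
  lines <- as_lines(lines)
  seen <- character(0)
  for (i in seq_along(lines)) {
    f <- split_fields(lines[i])
    if (length(f) != 4L)
      stop(sprintf("sidecar line %d: expected 4 tab-separated fields", i),
           call. = FALSE)
    if (!identical(f[1], doc$doc_id)) next
    score <- suppressWarnings(as.numeric(f[4]))
    if (is.na(score))
      stop(sprintf("sidecar line %d: non-numeric score '%s'", i, f[4]),
           call. = FALSE)
    ref <- strsplit(f[2], "#", fixed = TRUE)[[1]]
    if (length(ref) != 2L)
      stop(sprintf("sidecar line %d: malformed annotation ref '%s'", i, f[2]),
           call. = FALSE)
    if (f[2] %in% seen)
      stop(sprintf("sidecar line %d: duplicate row for '%s'", i, f[2]),
           call. = FALSE)
    seen <- c(seen, f[2])
    ev <- doc$events[[ref[1]]]
    if (is.null(ev))
      stop(sprintf("sidecar line %d: integrity error, unknown event '%s'",
                   i, ref[1]), call. = FALSE)
    if (identical(f[3], "trigger")) {
      ev$trigger_score <- score
    } else if (identical(f[3], "argument")) {
      idx <- suppressWarnings(as.integer(ref[2])) + 1L
      if (is.na(idx) || idx < 1L || idx > length(ev$roles))
        stop(sprintf("sidecar line %d: integrity error, argument index out of range for %s",
                     i, ref[1]), call. = FALSE)
      ev$arg_scores[idx] <- score
    } else {
      stop(sprintf("sidecar line %d: unknown kind '%s'", i, f[3]), call. = FALSE)
    }
    doc$events[[ref[1]]] <- ev
  }
  doc
}

## Serialize a document's raw scores as sidecar rows.  `event_map`
## applies the same id renumbering as write_standoff so the sidecar
## stays consistent with the emitted .a2 stream.
write_confidence_sidecar <- function(doc, event_map = NULL) {
  out <- character(0)
  for (eid in names(doc$events)) {
    ev <- doc$events[[eid]]
    out_id <- if (is.null(event_map)) eid else unname(event_map[eid])
    if (!is.na(ev$trigger_score))
      out <- c(out, sprintf("%s\t%s#trigger\ttrigger\t%s", doc$doc_id, out_id,
                            format(ev$trigger_score, digits = 17)))
    for (j in seq_along(ev$arg_scores))
      if (!is.na(ev$arg_scores[j]))
        out <- c(out, sprintf("%s\t%s#%d\targument\t%s", doc$doc_id, out_id,
                              j - 1L, format(ev$arg_scores[j], digits = 17)))
  }
  out
}

#' @export
print.standoff_document <- function(x, ...) {
  cat(sprintf("<standoff_document '%s': %d chars, %d mentions, %d events>\n",
              x$doc_id, nchar(x$text), nrow(x$mentions), length(x$events)))
  invisible(x)
}

#' Read a corpus directory
#'
#' A corpus is a directory with one `<doc_id>.txt` per document plus
#' matching `.a1` (entities), `.a2` (triggers and events, optional) and
#' `.conf.tsv` (confidence sidecar, optional) files.
#'
#' @param dir Directory path.
#' @param validate Passed to [read_standoff()].
#' @return A `standoff_corpus` (list of documents, named by doc id).
#' @export
read_corpus <- function(dir, validate = TRUE) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- list()
  for (txt in txts) {
    doc_id <- sub("\\.txt$", "", basename(txt))
    text <- readChar(txt, file.size(txt), useBytes = FALSE)
    Encoding(text) <- "UTF-8"
    read_or_empty <- function(path)
      if (file.exists(path)) readLines(path, encoding = "UTF-8") else character(0)
    a1 <- read_or_empty(file.path(dir, paste0(doc_id, ".a1")))
    a2 <- read_or_empty(file.path(dir, paste0(doc_id, ".a2")))
    doc <- read_standoff(a1, a2, text, doc_id = doc_id, validate = validate)
    conf <- file.path(dir, paste0(doc_id, ".conf.tsv"))
    if (file.exists(conf))
      doc <- read_confidence_sidecar(readLines(conf, encoding = "UTF-8"), doc)
    docs[[doc_id]] <- doc
  }
  structure(docs, class = "standoff_corpus")
}

#' Write a corpus directory
#'
#' @param corpus A `standoff_corpus`.
#' @param dir Output directory (created if needed).
#' @param sidecar Also write `.conf.tsv` files for documents carrying
#'   raw scores.
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, sidecar = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    base <- file.path(dir, doc$doc_id)
    writeChar(doc$text, paste0(base, ".txt"), eos = NULL, useBytes = FALSE)
    streams <- write_standoff(doc)
    writeLines(streams$entity_lines, paste0(base, ".a1"), useBytes = FALSE)
    writeLines(streams$event_lines, paste0(base, ".a2"), useBytes = FALSE)
    if (sidecar) {
      rows <- write_confidence_sidecar(doc, event_map = streams$event_map)
      if (length(rows)) writeLines(rows, paste0(base, ".conf.tsv"))
    }
  }
  invisible(dir)
}

#' @export
print.standoff_corpus <- function(x, ...) {
  cat(sprintf("<standoff_corpus: %d documents, %d events>\n", length(x),
              sum(vapply(x, function(d) length(d$events), integer(1)))))
  invisible(x)
}

## ---- resolved event trees -------------------------------------------------

## Ids of root events: events not referenced as an argument of any event.
root_event_ids <- function(doc) {
  eids <- names(doc$events)
  used <- unlist(lapply(doc$events, function(ev) ev$targets), use.names = FALSE)
  setdiff(eids, used)
}

#' Resolve a flat event annotation into an event tree
#'
#' @param doc A `standoff_document`.
#' @param event_id Event annotation id.
#' @return An event tree; gene leaves carry the mention surface as
#'   `symbol` and the mention id.
#' @export
resolve_event <- function(doc, event_id) {
  surf <- structure(doc$mentions$surface, names = doc$mentions$mention_id)
  build <- function(eid) {
    ev <- doc$events[[eid]]
    children <- lapply(ev$targets, function(t) {
      if (t %in% names(doc$events)) build(t) else ev_gene(surf[[t]], mention_id = t)
    })
    ev_event(ev$type, ev$roles, children, event_id = eid, trigger = ev$trigger_text)
  }
  build(event_id)
}

## Root structures of a corpus: refined trees when refinement has been
## run, raw resolved root events otherwise.
corpus_trees <- function(corpus) {
  out <- list()
  for (doc in corpus) {
    if (!is.null(doc$refined)) {
      out <- c(out, lapply(doc$refined, function(r) r$structure))
    } else {
      out <- c(out, lapply(root_event_ids(doc), function(e) resolve_event(doc, e)))
    }
  }
  out
}
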