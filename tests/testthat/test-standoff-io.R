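test_that("entity and event streams parse into a resolved document", {
  doc <- fixture_document()
  expect_s3_class(doc, "standoff_document")
  expect_equal(nrow(doc$mentions), 3L)
  expect_equal(doc$mentions$surface[1], "IL-2")
  expect_equal(length(doc$events), 2L)
  ev <- doc$events[["E1"]]
  expect_equal(ev$type, "positive_regulation")
  expect_equal(ev$roles, c("Cause", "Theme"))
  expect_equal(ev$targets, c("T1", "E2"))
  # the binding nests as the regulation's Theme
  tree <- resolve_event(doc, "E1")
  expect_equal(print_bracket(tree),
               "Positive-Regulation(C:IL-2, T:Binding(T:NF-kB, T:p55))")
})

test_that("mention surfaces always equal their text slice", {
  doc <- fixture_document()
  for (i in seq_len(nrow(doc$mentions)))
    expect_identical(substr(doc$text, doc$mentions$start[i] + 1,
                            doc$mentions$end[i]),
                     doc$mentions$surface[i])
  # a mismatching surface is rejected outright
  bad <- sub("IL-2$", "IL-X", fixture_entity_lines)
  expect_error(read_standoff(bad, fixture_event_lines, fixture_text),
               "does not match text slice")
})

test_that("empty streams yield an empty document", {
  doc <- read_standoff(character(0), character(0), "no annotations here")
  expect_equal(nrow(doc$mentions), 0L)
  expect_equal(length(doc$events), 0L)
  out <- write_standoff(doc)
  expect_length(out$entity_lines, 0L)
  expect_length(out$event_lines, 0L)
})

test_that("malformed lines and dangling references are rejected with positions", {
  expect_error(read_standoff("T1 Protein 0 4 IL-2", fixture_event_lines,
                             fixture_text),
               "line 1")
  expect_error(read_standoff(fixture_entity_lines,
                             c(fixture_event_lines[1:3],
                               "E2\tBinding:T5 Theme:T2 Theme:T99"),
                             fixture_text),
               "dangling|validation")
  expect_error(read_standoff(fixture_entity_lines,
                             c("E1\tPositive_regulation:T9 Theme:T1"),
                             fixture_text),
               "unknown trigger")
})

test_that("each constraint family has a violating and a passing fixture", {
  # passing: the known-good fixture
  expect_equal(nrow(validate_event_constraints(fixture_document())), 0L)

  make_doc <- function(event_lines) {
    read_standoff(fixture_entity_lines, event_lines, fixture_text,
                  validate = FALSE)
  }
  # (1) single-Theme physical type with an extra Cause
  v <- validate_event_constraints(make_doc(c(
    "T4\tPhosphorylation 5 13\tenhances",
    "E1\tPhosphorylation:T4 Theme:T2 Cause:T1")))
  expect_true("single-theme-type" %in% v$rule)
  expect_true("E1" %in% v$event_id)
  # (2) binding with a Cause argument
  v <- validate_event_constraints(make_doc(c(
    "T4\tBinding 14 21\tbinding",
    "E1\tBinding:T4 Theme:T2 Cause:T1")))
  expect_true("binding-no-cause" %in% v$rule)
  # (3) regulation with two Themes
  v <- validate_event_constraints(make_doc(c(
    "T4\tRegulation 5 13\tenhances",
    "E1\tRegulation:T4 Theme:T1 Theme:T2")))
  expect_true("regulation-args" %in% v$rule)
  # cyclic argument graph
  v <- validate_event_constraints(make_doc(c(
    "T4\tRegulation 5 13\tenhances",
    "T5\tRegulation 14 21\tbinding",
    "E1\tRegulation:T4 Theme:E2",
    "E2\tRegulation:T5 Theme:E1")))
  expect_true("acyclic" %in% v$rule)
})

test_that("write/read round-trips preserve structure up to id renaming", {
  doc <- fixture_document()
  out <- write_standoff(doc)
  doc2 <- read_standoff(out$entity_lines, out$event_lines, doc$text,
                        doc_id = doc$doc_id)
  expect_equal(doc2$mentions$surface, doc$mentions$surface)
  expect_equal(doc2$mentions$start, doc$mentions$start)
  roots1 <- sort(vapply(root_event_ids_pub(doc), function(e)
    print_bracket(resolve_event(doc, e)), character(1)))
  roots2 <- sort(vapply(root_event_ids_pub(doc2), function(e)
    print_bracket(resolve_event(doc2, e)), character(1)))
  expect_equal(roots1, roots2)

  # property: round trip over a generated corpus
  gen <- generate_corpus(generator_config(n_documents = 15, seed = 42))
  for (d in gen$corpus) {
    s <- write_standoff(d)
    d2 <- read_standoff(s$entity_lines, s$event_lines, d$text, doc_id = d$doc_id)
    r1 <- sort(vapply(root_event_ids_pub(d), function(e)
      print_bracket(resolve_event(d, e)), character(1)))
    r2 <- sort(vapply(root_event_ids_pub(d2), function(e)
      print_bracket(resolve_event(d2, e)), character(1)))
    expect_equal(r2, r1)
  }
})

test_that("confidence sidecars attach scores and reject bad rows", {
  doc <- fixture_document()
  rows <- c("fix01\tE1#trigger\ttrigger\t0.5",
            "fix01\tE1#0\targument\t0.2",
            "otherdoc\tE9#trigger\ttrigger\t1.0")  # ignored, other doc
  doc2 <- read_confidence_sidecar(rows, doc)
  expect_equal(doc2$events[["E1"]]$trigger_score, 0.5)
  expect_equal(doc2$events[["E1"]]$arg_scores, c(0.2, NA))
  expect_true(is.na(doc2$events[["E2"]]$trigger_score))

  expect_error(read_confidence_sidecar(
    c("fix01\tE1#trigger\ttrigger\t0.5", "fix01\tE1#trigger\ttrigger\t0.6"),
    doc), "duplicate")
  expect_error(read_confidence_sidecar("fix01\tE7#trigger\ttrigger\t0.5", doc),
               "unknown event")
  expect_error(read_confidence_sidecar("fix01\tE1#trigger\ttrigger\tabc", doc),
               "non-numeric")
  expect_error(read_confidence_sidecar("fix01\tE1#5\targument\t0.5", doc),
               "out of range")
  # empty sidecar leaves everything unset
  doc3 <- read_confidence_sidecar(character(0), doc)
  expect_true(all(is.na(vapply(doc3$events, function(e) e$trigger_score,
                               numeric(1)))))
})

test_that("corpus directories round-trip including sidecars", {
  dir <- withr::local_tempdir()
  gen <- generate_corpus(generator_config(n_documents = 8, seed = 3), dir = dir)
  corp <- read_corpus(dir)
  expect_length(corp, 8L)
  for (id in names(gen$corpus)) {
    a <- gen$corpus[[id]]; b <- corp[[id]]
    expect_identical(b$text, a$text)
    expect_equal(nrow(b$mentions), nrow(a$mentions))
    expect_equal(vapply(b$events, function(e) e$trigger_score, numeric(1)),
                 vapply(a$events, function(e) e$trigger_score, numeric(1)),
                 tolerance = 1e-12)
  }
})
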