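pair_table <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(key_a = r[[1]], key_b = r[[2]], cls = r[[3]],
               directed = !identical(r[[3]], "binding"),
               n_evidence = 1L,
               agg_score = if (length(r) >= 4) r[[4]] else NA_real_,
               category = NA_character_, best_doc = "d", best_event = "E1",
               stringsAsFactors = FALSE)))
  structure(list(pairs = df,
                 evidence = cbind(df[0, 1:4], data.frame(target = character(0),
                                                         doc_id = character(0),
                                                         event_id = character(0),
                                                         score = numeric(0))),
                 scheme = "canonical", bins = NULL),
            class = "gene_pairs")
}

test_that("the three join patterns produce their associations", {
  gp <- pair_table(list("mec1", "rad53", "regulation"),
                   list("rad9", "rad53", "regulation"))
  a <- derive_indirect(gp)
  expect_equal(nrow(a), 1L)
  expect_equal(a$kind, "coregulation")
  expect_equal(c(a$key_a, a$key_b), c("mec1", "rad9"))
  expect_equal(a$shared, "rad53")

  gp <- pair_table(list("z", "a", "regulation"), list("z", "b", "regulation"))
  a <- derive_indirect(gp)
  expect_equal(a$kind, "common_regulator")
  expect_equal(a$shared, "z")

  gp <- pair_table(list("a", "z", "binding"), list("b", "z", "binding"))
  a <- derive_indirect(gp)
  expect_equal(a$kind, "common_binding_partner")
  expect_equal(c(a$key_a, a$key_b), c("a", "b"))

  # disjoint pair sets join to nothing
  gp <- pair_table(list("a", "b", "regulation"), list("c", "d", "binding"))
  expect_equal(nrow(derive_indirect(gp)), 0L)
})

test_that("indirect-regulation edges join; shared partners are counted once", {
  gp <- pair_table(list("a", "z", "regulation"),
                   list("b", "z", "indirect_regulation"),
                   # b also regulates z directly: z must not count twice
                   list("b", "z", "regulation"))
  a <- derive_indirect(gp)
  co <- a[a$kind == "coregulation", ]
  expect_equal(nrow(co), 1L)
  expect_equal(co$n_shared, 1L)
  expect_equal(co$shared, "z")
})

test_that("capture seeds feed only the coregulation join", {
  gp <- pair_table(list("thrombin", "akt", "regulation"))
  gp$evidence <- data.frame(key_a = "egf", key_b = "thrombin",
                            cls = "coregulation_capture", directed = FALSE,
                            target = "akt", doc_id = "d", event_id = "E1",
                            score = NA_real_, stringsAsFactors = FALSE)
  a <- derive_indirect(gp)
  expect_equal(a$kind, "coregulation")
  expect_equal(c(a$key_a, a$key_b), c("egf", "thrombin"))
  expect_equal(a$shared, "akt")
  expect_false(any(a$kind %in% c("common_regulator", "common_binding_partner")))
})

test_that("the join matches a brute-force triple loop and is symmetric", {
  set.seed(808)
  genes <- paste0("g", 1:8)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    df <- data.frame(
      key_a = sample(genes, n, replace = TRUE),
      key_b = sample(genes, n, replace = TRUE),
      cls = sample(c("regulation", "indirect_regulation", "binding"), n,
                   replace = TRUE),
      stringsAsFactors = FALSE)
    df <- df[df$key_a != df$key_b, , drop = FALSE]
    df$directed <- df$cls != "binding"
    df$key_tmp_a <- ifelse(df$directed, df$key_a, pmin(df$key_a, df$key_b))
    df$key_tmp_b <- ifelse(df$directed, df$key_b, pmax(df$key_a, df$key_b))
    df$key_a <- df$key_tmp_a; df$key_b <- df$key_tmp_b
    df <- unique(df[, c("key_a", "key_b", "cls", "directed")])
    df$n_evidence <- 1L; df$agg_score <- NA_real_; df$category <- NA_character_
    df$best_doc <- "d"; df$best_event <- "E1"
    gp <- structure(list(pairs = df, evidence = data.frame(), scheme = "canonical",
                         bins = NULL), class = "gene_pairs")
    mine <- as.data.frame(derive_indirect(gp))
    ref <- brute_join(df)
    key <- function(x) sort(paste(x$kind, x$key_a, x$key_b, x$n_shared, x$shared))
    expect_identical(key(mine), key(ref))

    # symmetry: swapping binding endpoint storage changes nothing
    df2 <- df
    b <- df2$cls == "binding"
    tmp <- df2$key_a[b]; df2$key_a[b] <- df2$key_b[b]; df2$key_b[b] <- tmp
    gp2 <- structure(list(pairs = df2, evidence = data.frame(),
                          scheme = "canonical", bins = NULL),
                     class = "gene_pairs")
    expect_identical(key(as.data.frame(derive_indirect(gp2))), key(mine))
  }
})

test_that("ranking orders by shared count, then score, then keys", {
  a <- data.frame(
    kind = "coregulation",
    key_a = c("b", "a", "c", "a"), key_b = c("x", "x", "x", "y"),
    n_shared = c(2L, 5L, 2L, 2L),
    shared = "z", best_edge_score = c(0.1, 0.0, 0.9, 0.1),
    hypothetical = TRUE, stringsAsFactors = FALSE)
  r <- rank_associations(a)
  expect_equal(r$n_shared[1], 5L)
  expect_equal(r$key_a[2], "c")         # score 0.9 beats the 0.1 ties
  expect_equal(r$key_a[3:4], c("a", "b"))  # lexicographic among equal scores
  # deterministic across runs
  expect_identical(rank_associations(a), r)
  # single association ranks as itself
  expect_identical(rank_associations(a[2, ])$key_a, "a")
})

test_that("every association is flagged as hypothetical", {
  gp <- pair_table(list("a", "z", "regulation"), list("b", "z", "regulation"))
  a <- derive_indirect(gp)
  expect_true(all(a$hypothetical))
})
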