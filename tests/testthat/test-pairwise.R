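test_that("pair extraction reproduces the worked regulation cascade", {
  seeds <- extract_pairs(parse_bracket(
    "Pos(C:Thrombin, T:Pos(C:EGF, T:Phos(T:Akt)))"))
  reg <- seeds[seeds$cls == "regulation", ]
  expect_setequal(paste(reg$key_a, reg$key_b), c("Thrombin Akt", "EGF Akt"))
  # Thrombin–EGF is not a direct pair of any class but survives as a
  # coregulation seed over Akt
  direct <- seeds[seeds$cls != "coregulation_capture", ]
  expect_false(any(direct$key_a == "EGF" & direct$key_b == "Thrombin" |
                   direct$key_a == "Thrombin" & direct$key_b == "EGF"))
  cap <- seeds[seeds$cls == "coregulation_capture", ]
  expect_equal(nrow(cap), 1L)
  expect_equal(sort(c(cap$key_a, cap$key_b)), c("EGF", "Thrombin"))
  expect_equal(cap$target, "Akt")
})

test_that("a Cause-side Theme descendant is only an indirect regulator", {
  seeds <- extract_pairs(parse_bracket("Reg(C:Reg(C:G1, T:G2), T:G3)"))
  expect_setequal(paste(seeds$key_a, seeds$key_b, seeds$cls),
                  c("G1 G3 regulation",        # Cause-of-Cause stays direct
                    "G2 G3 indirect_regulation",
                    "G1 G2 regulation"))       # classified at their own LCA
})

test_that("binding Themes pair with each other and with the outer Cause", {
  seeds <- extract_pairs(parse_bracket("Pos(C:IL2, T:Binding(T:NFKB, T:p55))"))
  expect_setequal(paste(seeds$key_a, seeds$key_b, seeds$cls),
                  c("NFKB p55 binding",
                    "IL2 NFKB regulation",
                    "IL2 p55 regulation"))
  # binding keys are stored in lexicographic order
  b <- seeds[seeds$cls == "binding", ]
  expect_true(all(b$key_a <= b$key_b))
})

test_that("single-gene and self-pair structures yield no pairs", {
  expect_equal(nrow(extract_pairs(parse_bracket("Phos(T:Akt)"))), 0L)
  expect_equal(nrow(extract_pairs(parse_bracket("Pos(C:Akt, T:Akt)"))), 0L)
  seeds <- extract_pairs(parse_bracket("Pos(C:A, T:Binding(T:A, T:B))"))
  expect_false(any(seeds$key_a == seeds$key_b))
})

test_that("prevalent patterns map to their annotated pair classes", {
  cases <- list(
    list("Binding(T:A, T:B)",                       "binding",             FALSE),
    list("Reg(C:A, T:B)",                           "regulation",          TRUE),
    list("Pos(C:A, T:Phos(T:B))",                   "regulation",          TRUE),
    list("Reg(C:Reg(T:Phos(T:A)), T:Phos(T:B))",    "indirect_regulation", TRUE),
    list("Neg(C:Phos(T:A), T:B)",                   "indirect_regulation", TRUE),
    list("Pos(C:Phos(T:A), T:Phos(T:B))",           "indirect_regulation", TRUE))
  for (cs in cases) {
    seeds <- extract_pairs(parse_bracket(cs[[1]]))
    expect_equal(nrow(seeds), 1L, info = cs[[1]])
    expect_equal(seeds$cls, cs[[2]], info = cs[[1]])
    expect_equal(seeds$directed, cs[[3]], info = cs[[1]])
    expect_equal(paste(seeds$key_a, seeds$key_b), "A B", info = cs[[1]])
  }
})

test_that("extraction agrees with the naive per-pair walker on random trees", {
  set.seed(606)
  for (i in 1:300) {
    tree <- refine_event(random_reg_tree(max_depth = 4))$structure
    expect_identical(seed_key(extract_pairs(tree)),
                     seed_key(naive_pair_walk(tree)),
                     info = print_bracket(tree))
  }
})

test_that("aggregation pools evidence and keeps directions distinct", {
  d1 <- doc_from_bracket("Pos(C:mec1, T:rad9)", "d1")
  d2 <- doc_from_bracket("Reg(C:mec1, T:rad9)", "d2")
  d3 <- doc_from_bracket("Neg(C:rad9, T:mec1)", "d3")
  corpus <- structure(list(d1 = d1, d2 = d2, d3 = d3),
                      class = "standoff_corpus")
  corpus <- refine_corpus(canonicalize_corpus(corpus))
  gp <- aggregate_pairs(corpus)
  expect_equal(nrow(gp$pairs), 2L)
  fwd <- gp$pairs[gp$pairs$key_a == "mec1", ]
  expect_equal(fwd$n_evidence, 2L)       # two documents, one pair
  rev <- gp$pairs[gp$pairs$key_a == "rad9", ]
  expect_equal(rev$n_evidence, 1L)       # opposite direction stays distinct
})

test_that("family schemes pool evidence for homologous symbols", {
  d1 <- doc_from_bracket("Pos(C:mec1, T:rad9)", "d1")
  d2 <- doc_from_bracket("Pos(C:atr, T:rad9)", "d2")
  corpus <- structure(list(d1 = d1, d2 = d2), class = "standoff_corpus")
  corpus <- refine_corpus(canonicalize_corpus(corpus))
  sc <- family_scheme("fam", c("mec1", "atr"), c("F42", "F42"))
  gp_can <- aggregate_pairs(corpus, scheme = "canonical")
  gp_fam <- aggregate_pairs(corpus, scheme = sc)
  expect_equal(nrow(gp_can$pairs), 2L)
  expect_equal(nrow(gp_fam$pairs), 1L)
  expect_equal(gp_fam$pairs$key_a, "F42")
  expect_equal(gp_fam$pairs$n_evidence, 2L)
})

test_that("aggregate scores average evidence and drive categories", {
  docs <- list()
  # six regulation pairs with staggered raw scores to span a range
  for (i in 1:6) {
    d <- doc_from_bracket(sprintf("Pos(C:g%d, T:h%d)", i, i), sprintf("s%d", i))
    d$events[["E1"]]$trigger_score <- i
    d$events[["E1"]]$arg_scores <- c(i, i)
    docs[[d$doc_id]] <- d
  }
  corpus <- structure(docs, class = "standoff_corpus")
  corpus <- score_corpus(refine_corpus(canonicalize_corpus(corpus)))
  gp <- aggregate_pairs(corpus)
  expect_equal(nrow(gp$pairs), 6L)
  expect_false(any(is.na(gp$pairs$agg_score)))
  # order consistency between scores and labels
  ord <- order(gp$pairs$agg_score)
  lv <- as.integer(factor(gp$pairs$category,
                          levels = c("very_low", "low", "average",
                                     "high", "very_high"), ordered = TRUE))
  expect_true(all(diff(lv[ord]) >= 0))
  # thresholding drops low-confidence pairs
  kept <- filter_pairs(gp, min_score = gp$pairs$agg_score[ord][3])
  expect_equal(nrow(kept$pairs), 4L)
  sweep <- threshold_sweep(gp, step = 0.05)
  expect_true(all(diff(sweep$n_kept) <= 0))
})
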