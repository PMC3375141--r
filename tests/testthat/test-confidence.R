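# A tiny corpus with hand-picked raw margins: three events, trigger
# scores {1,2,3}, argument scores {0,2,4}.
conf_corpus <- function(tr = c(1, 2, 3), ar = c(0, 2, 4)) {
  doc <- doc_from_bracket("Phos(T:a)")
  docs <- list()
  for (i in seq_along(tr)) {
    d <- doc
    d$doc_id <- sprintf("c%02d", i)
    d$events[["E1"]]$trigger_score <- tr[i]
    d$events[["E1"]]$arg_scores <- ar[i]
    docs[[d$doc_id]] <- d
  }
  structure(docs, class = "standoff_corpus")
}

test_that("normalization is population z-scoring per classifier kind", {
  corpus <- conf_corpus()
  p <- fit_normalization(corpus)
  expect_equal(p$trigger$mean, 2)
  expect_equal(p$trigger$sd, sqrt(2 / 3))       # population sd of {1,2,3}
  expect_equal(p$argument$mean, 2)
  expect_equal(p$argument$sd, sqrt(8 / 3))
  z <- (c(1, 2, 3) - p$trigger$mean) / p$trigger$sd
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(mean(z), 0)
  expect_equal(sqrt(mean(z^2)), 1)
  # already-standardized scores give the identity transform
  p2 <- fit_normalization(conf_corpus(tr = c(-1.2247449, 0, 1.2247449),
                                      ar = c(-1, 0, 1) * sqrt(3 / 2)))
  expect_equal(p2$trigger$mean, 0, tolerance = 1e-6)
  expect_equal(p2$trigger$sd, 1, tolerance = 1e-6)
  # all-identical scores are a degenerate corpus
  expect_error(fit_normalization(conf_corpus(tr = c(1, 1, 1))),
               "degenerate")
})

test_that("occurrence score is the minimum normalized component", {
  p <- structure(list(trigger = list(mean = 0, sd = 1),
                      argument = list(mean = 0, sd = 1)),
                 class = "norm_params")
  ev <- list(trigger_score = 0.5, arg_scores = c(0.2, 0.9))
  expect_equal(score_occurrence(ev, p), 0.2)
  ev2 <- list(trigger_score = -1.0, arg_scores = 0.3)
  expect_equal(score_occurrence(ev2, p), -1.0)
  ev3 <- list(trigger_score = 0.7, arg_scores = c(0.7, 0.7))
  expect_equal(score_occurrence(ev3, p), 0.7)
  # missing components leave the event unscored
  ev4 <- list(trigger_score = NA_real_, arg_scores = 0.3)
  expect_true(is.na(score_occurrence(ev4, p)))
})

test_that("generalized score is the mean of scored occurrences", {
  expect_equal(score_generalized(c(0.2, 0.4)), 0.3)
  expect_equal(score_generalized(0.7), 0.7)
  expect_equal(score_generalized(c(-1, 1)), 0)
  expect_equal(score_generalized(c(0.2, NA, 0.4)), 0.3)  # NA excluded
  expect_true(is.na(score_generalized(c(NA_real_, NA_real_))))
})

test_that("range binning splits the observed range into five 20% bins", {
  bins <- confidence_bins(c(-1, 1, 0.3, -0.2), mode = "range")
  expect_equal(bins$breaks, seq(-1, 1, length.out = 6))
  expect_equal(as.character(categorize(0.9, bins)), "very_high")  # [0.6, 1]
  expect_equal(as.character(categorize(-1, bins)), "very_low")
  expect_equal(as.character(categorize(1, bins)), "very_high")    # top bin closed
  # the top category spans exactly 20% of the confidence range
  expect_equal(bins$breaks[6] - bins$breaks[5], 0.4)
  expect_equal((bins$breaks[6] - bins$breaks[5]) /
                 (bins$breaks[6] - bins$breaks[1]), 0.2)
})

test_that("uniformly spaced scores land 20 per category in both modes", {
  x <- seq(-3, 7, length.out = 100)
  for (mode in c("range", "quantile")) {
    bins <- confidence_bins(x, mode = mode)
    tab <- table(categorize(x, bins))
    expect_equal(unname(as.integer(tab)), rep(20L, 5))
  }
})

test_that("degenerate single-score sets label everything average", {
  bins <- confidence_bins(c(0.5, 0.5, 0.5))
  expect_equal(as.character(categorize(0.5, bins)), "average")
})

test_that("categories are order-consistent and scoring is monotone", {
  set.seed(77)
  p <- structure(list(trigger = list(mean = 0, sd = 1),
                      argument = list(mean = 0, sd = 1)),
                 class = "norm_params")
  for (i in 1:200) {
    tr <- rnorm(1); ar <- rnorm(2)
    base <- score_occurrence(list(trigger_score = tr, arg_scores = ar), p)
    bump <- runif(1, 0, 2)
    k <- sample(1:3, 1)
    tr2 <- tr + if (k == 1) bump else 0
    ar2 <- ar + c(k == 2, k == 3) * bump
    raised <- score_occurrence(list(trigger_score = tr2, arg_scores = ar2), p)
    expect_gte(raised, base)
  }
  scores <- rnorm(50)
  bins <- confidence_bins(scores)
  cats <- categorize(scores, bins)
  ord <- order(scores)
  expect_true(all(diff(as.integer(cats[ord])) >= 0))
})

test_that("adding a constant to all raw trigger scores leaves norm scores unchanged", {
  corpus <- conf_corpus()
  s1 <- vapply(score_corpus(corpus)[[1]]$events, function(e) e$norm_score,
               numeric(1))
  shifted <- conf_corpus(tr = c(1, 2, 3) + 57)
  s2 <- vapply(score_corpus(shifted)[[1]]$events, function(e) e$norm_score,
               numeric(1))
  expect_equal(s2, s1)
})
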