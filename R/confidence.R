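## Confidence scoring.
##
## Raw classifier margins (distances to a linear SVM's decision
## hyperplane) come from two separate classifiers — one predicting event
## triggers, one predicting arguments — and are not mutually comparable.
## They are z-normalized corpus-wide, separately per kind, using the
## population standard deviation.  An event occurrence's confidence is
## the minimum of its normalized component scores (a fuzzy-AND: every
## decision involved must be confident); a generalized event's score is
## the mean over its scored occurrences.

#' Fit corpus-wide score normalization parameters
#'
#' @param corpus A `standoff_corpus` with raw scores attached (see
#'   [read_confidence_sidecar()]).
#' @return A `norm_params` object: per kind (`trigger`, `argument`) the
#'   corpus mean and population standard deviation.
#' @export
fit_normalization <- function(corpus) {
  triggers <- unlist(lapply(corpus, function(d)
    vapply(d$events, function(ev) ev$trigger_score, numeric(1))),
    use.names = FALSE)
  args <- unlist(lapply(corpus, function(d)
    lapply(d$events, function(ev) ev$arg_scores)), use.names = FALSE)
  fit1 <- function(x, kind) {
    x <- x[!is.na(x)]
    if (length(unique(x)) < 2L)
      stop(sprintf("degenerate corpus: need >= 2 distinct raw %s scores", kind),
           call. = FALSE)
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))  # population sd
    list(mean = m, sd = s)
  }
  structure(list(trigger = fit1(triggers, "trigger"),
                 argument = fit1(args, "argument")),
            class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat(sprintf("<norm_params: trigger mean %.4g sd %.4g; argument mean %.4g sd %.4g>\n",
              x$trigger$mean, x$trigger$sd, x$argument$mean, x$argument$sd))
  invisible(x)
}

z_score <- function(x, p) (x - p$mean) / p$sd

#' Confidence of a single event occurrence
#'
#' The minimum of the normalized trigger score and all normalized
#' argument scores.  Events missing any component score are unscored
#' (`NA`) and rank last.
#'
#' @param event An event record from a `standoff_document`.
#' @param params A `norm_params` object.
#' @return A single numeric score, or `NA`.
#' @export
score_occurrence <- function(event, params) {
  comps <- c(z_score(event$trigger_score, params$trigger),
             z_score(event$arg_scores, params$argument))
  if (length(comps) == 0L || anyNA(comps)) return(NA_real_)
  min(comps)
}

#' Attach normalized occurrence scores across a corpus
#'
#' Fills `norm_score` for every event of every document.  Refined
#' structures, when present, inherit the score of their original
#' occurrence.
#'
#' @param corpus A `standoff_corpus`.
#' @param params A `norm_params` object; fitted from the corpus when
#'   omitted.
#' @return The scored corpus.
#' @export
score_corpus <- function(corpus, params = NULL) {
  if (is.null(params)) params <- fit_normalization(corpus)
  for (i in seq_along(corpus)) {
    for (eid in names(corpus[[i]]$events)) {
      corpus[[i]]$events[[eid]]$norm_score <-
        score_occurrence(corpus[[i]]$events[[eid]], params)
    }
    if (!is.null(corpus[[i]]$refined)) {
      for (k in seq_along(corpus[[i]]$refined)) {
        oid <- corpus[[i]]$refined[[k]]$original_id
        corpus[[i]]$refined[[k]]$norm_score <- corpus[[i]]$events[[oid]]$norm_score
      }
    }
  }
  attr(corpus, "norm_params") <- params
  corpus
}

#' Confidence of a generalized event
#'
#' The arithmetic mean of its scored occurrences; unscored occurrences
#' are excluded from the mean (but still count as evidence).
#'
#' @param occurrence_scores Numeric vector of occurrence scores, may
#'   contain `NA`.
#' @return The mean score, or `NA` when no occurrence is scored.
#' @export
score_generalized <- function(occurrence_scores) {
  x <- occurrence_scores[!is.na(occurrence_scores)]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

CONFIDENCE_LABELS <- c("very_low", "low", "average", "high", "very_high")

#' Five-category confidence bins
#'
#' Splits the observed scores into five categories, `very_low` up to
#' `very_high`.  In `"range"` mode (the default) the observed
#' `[min, max]` range is split into five equal-width bins, so the top
#' category spans the top 20% of the confidence range; in `"quantile"`
#' mode the bin boundaries are the empirical 20/40/60/80% quantiles, so
#' each category holds about 20% of the events.  A degenerate
#' single-value score set yields the single category `average`.
#'
#' @param scores Numeric vector of (generalized) scores; `NA` ignored.
#' @param mode `"range"` or `"quantile"`.
#' @return A `confidence_bins` object holding the six boundaries.
#' @export
confidence_bins <- function(scores, mode = c("range", "quantile")) {
  mode <- match.arg(mode)
  x <- scores[!is.na(scores)]
  if (length(x) == 0L) stop("no scores to bin", call. = FALSE)
  degenerate <- length(unique(x)) == 1L
  breaks <- if (degenerate) rep(x[1], 6)
            else if (mode == "range") seq(min(x), max(x), length.out = 6)
            else unname(stats::quantile(x, probs = seq(0, 1, by = 0.2), type = 7))
  structure(list(breaks = breaks, mode = mode, degenerate = degenerate),
            class = "confidence_bins")
}

#' @export
print.confidence_bins <- function(x, ...) {
  cat(sprintf("<confidence_bins (%s): %s>\n", x$mode,
              paste(format(x$breaks, digits = 4), collapse = " | ")))
  invisible(x)
}

#' Assign confidence categories to scores
#'
#' @param scores Numeric vector.
#' @param bins A `confidence_bins` object (see [confidence_bins()]).
#' @return An ordered factor with levels `very_low < low < average <
#'   high < very_high`; `NA` scores stay `NA`.  The top bin is closed;
#'   scores outside the fitted range are clamped to the outer bins.
#' @export
categorize <- function(scores, bins) {
  stopifnot(inherits(bins, "confidence_bins"))
  if (bins$degenerate) {
    lab <- ifelse(is.na(scores), NA_character_, "average")
  } else {
    idx <- findInterval(scores, bins$breaks, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), 5L)
    lab <- ifelse(is.na(scores), NA_character_, CONFIDENCE_LABELS[idx])
  }
  factor(lab, levels = CONFIDENCE_LABELS, ordered = TRUE)
}
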