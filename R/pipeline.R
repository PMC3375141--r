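## Full pipeline driver: read -> validate -> canonicalize -> refine ->
## score -> pairs -> indirect associations -> stats -> exports, with a
## JSON run manifest for reproducibility.

md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

corpus_md5 <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(txt|a1|a2|tsv)$",
                           full.names = TRUE))
  if (length(files) == 0L) return(NA_character_)
  md5_of_string(paste(basename(files), unname(tools::md5sum(files)),
                      collapse = "\n"))
}

#' Run the full post-processing pipeline
#'
#' Reads (or accepts) a standoff corpus, validates it, canonicalizes
#' mention surfaces, refines nested regulation chains, attaches
#' normalized confidence scores when raw margins are available,
#' aggregates typed gene pairs under the chosen generalization scheme,
#' derives and ranks indirect associations, and computes signature and
#' coverage tables.  When `out_dir` is given, all tables are exported
#' as deterministic TSV/SIF files together with a JSON run manifest.
#'
#' @param corpus A `standoff_corpus`, or a corpus directory path.
#' @param out_dir Optional output directory for exports.
#' @param scheme `"canonical"` or a `family_scheme` used for pair
#'   aggregation.
#' @param schemes List of `family_scheme`s for the coverage table.
#' @param lexicon Affix lexicon for canonicalization.
#' @param bin_mode Confidence binning mode, `"range"` or `"quantile"`.
#' @param min_score Optional confidence threshold; pairs scoring below
#'   it are dropped before the association join.
#' @return Invisibly, a list with `corpus`, `pairs`, `associations`,
#'   `signatures`, `coverage`, and `manifest`.
#' @export
run_pipeline <- function(corpus, out_dir = NULL, scheme = "canonical",
                         schemes = list(), lexicon = default_affix_lexicon(),
                         bin_mode = "range", min_score = NULL) {
  corpus_hash <- NA_character_
  if (is.character(corpus)) {
    corpus_hash <- corpus_md5(corpus)
    corpus <- read_corpus(corpus)
  }
  if (inherits(scheme, "family_scheme") &&
      !any(vapply(schemes, function(s) identical(s$name, scheme$name),
                  logical(1))))
    schemes <- c(schemes, list(scheme))

  corpus <- canonicalize_corpus(corpus, lexicon)
  corpus <- refine_corpus(corpus)

  has_scores <- any(unlist(lapply(corpus, function(d)
    vapply(d$events, function(ev) !is.na(ev$trigger_score), logical(1)))))
  params <- NULL
  if (has_scores) {
    params <- fit_normalization(corpus)
    corpus <- score_corpus(corpus, params)
  }

  gp <- aggregate_pairs(corpus, scheme = scheme, bin_mode = bin_mode)
  if (!is.null(min_score)) gp <- filter_pairs(gp, min_score)
  assocs <- rank_associations(derive_indirect(gp))
  sigs <- count_signatures(corpus)
  cov <- coverage_stats(corpus, schemes)

  manifest <- list(
    tool = "bioeventnet",
    version = as.character(utils::packageVersion("bioeventnet")),
    corpus_hash = corpus_hash,
    scheme = scheme_name(scheme),
    bin_mode = bin_mode,
    min_score = min_score,
    normalization = if (is.null(params)) NULL else
      list(trigger = params$trigger, argument = params$argument),
    category_boundaries = if (is.null(gp$bins)) NULL else gp$bins$breaks,
    counts = list(
      documents = length(corpus),
      events = sum(vapply(corpus, function(d) length(d$events), integer(1))),
      mentions = sum(vapply(corpus, function(d) nrow(d$mentions), integer(1))),
      refined_structures = sum(vapply(corpus, function(d) length(d$refined),
                                      integer(1))),
      pairs = nrow(gp$pairs),
      associations = nrow(assocs)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pairs_tsv(gp, file.path(out_dir, "pairs.tsv"))
    write_associations_tsv(assocs, file.path(out_dir, "associations.tsv"))
    write_sif(assocs, file.path(out_dir, "associations.sif"))
    write_signature_tsv(sigs, file.path(out_dir, "signatures.tsv"))
    write_coverage_tsv(cov, file.path(out_dir, "coverage.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(corpus = corpus, pairs = gp, associations = assocs,
                 signatures = sigs, coverage = cov, manifest = manifest))
}
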