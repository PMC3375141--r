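## Deterministic TSV exports.  Numbers are printed with a fixed format
## so that identical inputs yield byte-identical files.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))

write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(unname(df), sep = "\t")))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Export an aggregated pair table as TSV
#'
#' Columns: `key_a`, `key_b`, `class`, `direction`, `n_evidence`,
#' `agg_score`, `category`, `best_doc`, `best_event`.
#'
#' @param gp A `gene_pairs` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pairs_tsv <- function(gp, path) {
  p <- gp$pairs
  out <- data.frame(key_a = p$key_a, key_b = p$key_b, class = p$cls,
                    direction = ifelse(p$directed, "a>b", "undirected"),
                    n_evidence = p$n_evidence, agg_score = p$agg_score,
                    category = p$category, best_doc = p$best_doc,
                    best_event = p$best_event, stringsAsFactors = FALSE)
  write_tsv_det(out, path)
}

#' Export indirect associations as TSV
#'
#' @param assocs An `indirect_associations` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations_tsv <- function(assocs, path) {
  write_tsv_det(as.data.frame(assocs), path)
}

#' Export associations as a SIF-style edge list
#'
#' One line per association: `key_a<TAB>kind<TAB>key_b`, suitable for
#' network tools.
#'
#' @param assocs An `indirect_associations` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(assocs, path) {
  lines <- sprintf("%s\t%s\t%s", assocs$key_a, assocs$kind, assocs$key_b)
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Export a signature table as TSV
#'
#' @param sig_table Output of [count_signatures()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(sig_table, path) {
  write_tsv_det(sig_table, path)
}

#' Export coverage statistics as TSV
#'
#' @param cov Output of [coverage_stats()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_tsv <- function(cov, path) {
  write_tsv_det(cov, path)
}
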