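## Gene-symbol canonicalization and family generalization.
##
## A mention surface such as "human Esr-1 subunit" is reduced to the
## core symbol "esr1" by iteratively stripping superfluous affix tokens
## from both ends, then discarding non-alphanumeric characters and
## lowercasing.  Canonical symbols may then be generalized to gene-family
## keys under one or more mapping schemes.

#' Construct an affix lexicon
#'
#' The lexicon lists whitespace-separated tokens considered superfluous
#' context around a gene symbol: species adjectives and structural words
#' on either side.  Tokens are matched case-insensitively against the
#' alphanumeric core of each surface token.
#'
#' @param prefixes,suffixes Character vectors of lowercase tokens.
#' @return An `affix_lexicon`.
#' @export
affix_lexicon <- function(prefixes = character(0), suffixes = character(0)) {
  chk <- function(x, what) {
    x <- as.character(x)
    if (any(!nzchar(x)) || any(x != tolower(x)))
      stop(sprintf("%s tokens must be non-empty and lowercase", what),
           call. = FALSE)
    x
  }
  structure(list(prefixes = chk(prefixes, "prefix"),
                 suffixes = chk(suffixes, "suffix")),
            class = "affix_lexicon")
}

#' Default affix lexicon
#'
#' Seeds the lexicon with common species adjectives and structural words
#' observed around gene symbols in abstracts.
#'
#' @return An `affix_lexicon`.
#' @export
default_affix_lexicon <- function() {
  species <- c("human", "murine", "mouse", "rat", "yeast", "bovine",
               "bacterial", "plant", "mammalian", "recombinant")
  structural <- c("protein", "gene", "subunit", "promoter", "receptor",
                  "mrna", "kinase", "factor", "complex", "homolog")
  affix_lexicon(prefixes = c(species, "the"),
                suffixes = structural)
}

#' Read an affix lexicon from a YAML file
#'
#' The file holds two lists, `prefixes` and `suffixes`.
#'
#' @param path Path to a YAML file.
#' @return An `affix_lexicon`.
#' @export
read_affix_lexicon <- function(path) {
  y <- yaml::read_yaml(path)
  affix_lexicon(prefixes = unlist(y$prefixes), suffixes = unlist(y$suffixes))
}

## Alphanumeric core of a string: drop everything outside [A-Za-z0-9]
## (Greek letters and other non-ASCII characters are dropped, not
## transliterated), lowercase the rest.
alnum_core <- function(x) tolower(gsub("[^A-Za-z0-9]+", "", x, perl = TRUE))

#' Canonicalize gene-mention surfaces
#'
#' Strips affix-lexicon tokens iteratively from both ends of the
#' whitespace-tokenized surface, removes non-alphanumeric characters
#' from what remains, and lowercases.  If stripping empties the string,
#' the result falls back to the lowercased alphanumeric core of the
#' original surface.  Surfaces with no alphanumeric characters at all
#' are uncanonicalizable and yield `NA` (they are excluded from
#' generalization).  The operation is idempotent.
#'
#' @param surface Character vector of mention surfaces.
#' @param lex An `affix_lexicon`; defaults to [default_affix_lexicon()].
#' @return Character vector of canonical symbols (`NA` where
#'   uncanonicalizable), matching `^[a-z0-9]+$` elsewhere.
#' @examples
#' canonicalize("human Esr-1 subunit")  # "esr1"
#' @export
canonicalize <- function(surface, lex = default_affix_lexicon()) {
  stopifnot(inherits(lex, "affix_lexicon"))
  one <- function(s) {
    if (!nzchar(s)) stop("surface must be non-empty", call. = FALSE)
    toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
    cores <- alnum_core(toks)
    lo <- 1L; hi <- length(toks)
    repeat {
      moved <- FALSE
      while (lo <= hi && cores[lo] %in% lex$prefixes) { lo <- lo + 1L; moved <- TRUE }
      while (hi >= lo && cores[hi] %in% lex$suffixes) { hi <- hi - 1L; moved <- TRUE }
      if (!moved || lo > hi) break
    }
    out <- if (lo <= hi) paste(cores[lo:hi], collapse = "") else ""
    if (!nzchar(out)) out <- paste(cores, collapse = "")  # stripping emptied it
    if (!nzchar(out)) return(NA_character_)               # no alphanumerics at all
    out
  }
  vapply(surface, one, character(1), USE.NAMES = FALSE)
}

#' Construct a family-generalization scheme
#'
#' A scheme maps canonical gene symbols (many-to-one) onto family
#' identifiers, in the manner of homology or gene-family resources.
#' When a symbol is claimed by several families, the tie is resolved at
#' construction time in favour of the family with the most member
#' symbols, ties broken by lexicographic family id.
#'
#' @param name Scheme name (e.g. `"homologene_like"`).
#' @param symbols Character vector of canonical symbols
#'   (`^[a-z0-9]+$`).
#' @param families Character vector of family ids, parallel to
#'   `symbols`.
#' @param provenance Free-text description of the mapping's origin.
#' @return A `family_scheme`.
#' @export
family_scheme <- function(name, symbols, families, provenance = "") {
  stopifnot(length(symbols) == length(families))
  symbols <- as.character(symbols); families <- as.character(families)
  if (any(!grepl("^[a-z0-9]+$", symbols)))
    stop("scheme mapping keys must match ^[a-z0-9]+$", call. = FALSE)
  df <- unique(data.frame(symbol = symbols, family = families,
                          stringsAsFactors = FALSE))
  size <- table(df$family)
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup)) {
    keep <- logical(nrow(df))
    for (s in unique(df$symbol)) {
      idx <- which(df$symbol == s)
      if (length(idx) == 1L) { keep[idx] <- TRUE; next }
      fams <- df$family[idx]
      ord <- order(-as.integer(size[fams]), fams)
      keep[idx[ord[1]]] <- TRUE
    }
    df <- df[keep, , drop = FALSE]
  }
  mapping <- structure(df$family, names = df$symbol)
  structure(list(name = name, mapping = mapping, provenance = provenance),
            class = "family_scheme")
}

#' Read a family scheme from a TSV mapping file
#'
#' Rows are `canonical<TAB>family_id`; lines starting with `#` are
#' skipped.
#'
#' @param path Path to a TSV file.
#' @param name Scheme name; defaults to the file name without extension.
#' @return A `family_scheme`.
#' @export
read_family_scheme <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("symbol", "family"),
                          colClasses = "character")
  family_scheme(name, df$symbol, df$family,
                provenance = paste("file:", path))
}

#' Look up a canonical symbol's family under a scheme
#'
#' @param canonical Character vector of canonical symbols.
#' @param scheme A `family_scheme`.
#' @return Character vector of family ids, `"unmapped"` where the
#'   symbol is absent from the mapping.
#' @export
assign_family <- function(canonical, scheme) {
  stopifnot(inherits(scheme, "family_scheme"))
  out <- unname(scheme$mapping[canonical])
  out[is.na(out)] <- "unmapped"
  out
}

#' Generalization key of a canonical symbol
#'
#' Under the `"canonical"` scheme the key is the canonical symbol
#' itself; under a family scheme it is the family id, falling back to
#' the canonical symbol (its own singleton key) when unmapped.
#'
#' @param canonical Character vector of canonical symbols.
#' @param scheme `"canonical"`, or a `family_scheme`.
#' @return Character vector of generalization keys.
#' @export
generalization_key <- function(canonical, scheme = "canonical") {
  if (identical(scheme, "canonical")) return(canonical)
  if (!inherits(scheme, "family_scheme"))
    stop("unknown generalization scheme; use \"canonical\" or a family_scheme",
         call. = FALSE)
  fam <- assign_family(canonical, scheme)
  ifelse(fam == "unmapped", canonical, fam)
}

#' Canonicalize every mention in a corpus
#'
#' Fills the `canonical` column of each document's mention table.
#'
#' @param corpus A `standoff_corpus`.
#' @param lex An `affix_lexicon`.
#' @return The corpus with canonical symbols filled.
#' @export
canonicalize_corpus <- function(corpus, lex = default_affix_lexicon()) {
  for (i in seq_along(corpus)) {
    if (nrow(corpus[[i]]$mentions) > 0L)
      corpus[[i]]$mentions$canonical <- canonicalize(corpus[[i]]$mentions$surface, lex)
  }
  corpus
}

#' Gene-symbol coverage statistics under family schemes
#'
#' For each scheme, reports how many distinct canonical symbols in the
#' corpus are mapped to a family, and how many mention occurrences those
#' symbols cover.  The canonical row covers 100% by construction.
#'
#' @param corpus A canonicalized `standoff_corpus`.
#' @param schemes A list of `family_scheme` objects.
#' @return A data.frame with columns `scheme`, `distinct_total`,
#'   `distinct_mapped`, `pct_distinct`, `occ_total`, `occ_mapped`,
#'   `pct_occ`.
#' @export
coverage_stats <- function(corpus, schemes = list()) {
  canon <- unlist(lapply(corpus, function(d) d$mentions$canonical),
                  use.names = FALSE)
  canon <- canon[!is.na(canon)]
  occ_total <- length(canon)
  freq <- table(canon)
  distinct_total <- length(freq)
  row <- function(scheme_name, mapped_symbols) {
    dm <- sum(names(freq) %in% mapped_symbols)
    om <- sum(freq[names(freq) %in% mapped_symbols])
    data.frame(scheme = scheme_name,
               distinct_total = distinct_total, distinct_mapped = dm,
               pct_distinct = if (distinct_total) 100 * dm / distinct_total else 0,
               occ_total = occ_total, occ_mapped = om,
               pct_occ = if (occ_total) 100 * om / occ_total else 0,
               stringsAsFactors = FALSE)
  }
  out <- row("canonical", names(freq))
  for (sc in schemes) out <- rbind(out, row(sc$name, names(sc$mapping)))
  rownames(out) <- NULL
  out
}
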