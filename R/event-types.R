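#' @keywords internal
"_PACKAGE"

## The nine event types of the ST'09-style event model, in internal
## lowercase snake_case form.  Writers emit ST-style capitalised names.
EVENT_TYPES <- c(
  "gene_expression", "transcription", "localization",
  "protein_catabolism", "phosphorylation",
  "binding",
  "regulation", "positive_regulation", "negative_regulation"
)

## Single-Theme "physical" types: exactly one Theme argument, a gene mention.
SINGLE_THEME_TYPES <- c(
  "gene_expression", "transcription", "localization",
  "protein_catabolism", "phosphorylation"
)

## Regulation-class types: one Theme, at most one Cause, arguments may nest.
REGULATION_TYPES <- c("regulation", "positive_regulation", "negative_regulation")

#' Test whether an event type belongs to the regulation class
#'
#' Regulation-class events (unspecified, positive or negative regulation)
#' are the only events whose arguments may recursively be other events,
#' and the only removable unit of the refinement rewrite system.
#'
#' @param type Character vector of internal event type names.
#' @return Logical vector.
#' @export
is_regulation_type <- function(type) type %in% REGULATION_TYPES

#' Test whether an event type is a single-Theme physical type
#'
#' @param type Character vector of internal event type names.
#' @return Logical vector.
#' @export
is_physical_type <- function(type) type %in% SINGLE_THEME_TYPES

## ST-style names used in .a2 files (capitalised, underscored).
st_type_name <- function(type) {
  paste0(toupper(substring(type, 1, 1)), substring(type, 2))
}

## Map an external type token (ST name, bracket-notation name, or shorthand)
## to the internal snake_case name; NA when unknown.
normalize_type_name <- function(token) {
  key <- tolower(gsub("[-_ ]", "", token))
  alias <- c(
    geneexpression     = "gene_expression",
    expression         = "gene_expression",
    transcription      = "transcription",
    localization       = "localization",
    proteincatabolism  = "protein_catabolism",
    catabolism         = "protein_catabolism",
    phosphorylation    = "phosphorylation",
    phos               = "phosphorylation",
    binding            = "binding",
    bind               = "binding",
    regulation         = "regulation",
    reg                = "regulation",
    positiveregulation = "positive_regulation",
    posreg             = "positive_regulation",
    pos                = "positive_regulation",
    negativeregulation = "negative_regulation",
    negreg             = "negative_regulation",
    neg                = "negative_regulation"
  )
  out <- unname(alias[key])
  out
}

## Display name used by the bracket notation, e.g. "Positive-Regulation".
bracket_type_name <- function(type) {
  parts <- strsplit(type, "_", fixed = TRUE)[[1]]
  paste(vapply(parts, function(p) {
    paste0(toupper(substring(p, 1, 1)), substring(p, 2))
  }, character(1)), collapse = "-")
}
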