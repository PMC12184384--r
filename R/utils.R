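#' Normalize a term or drug-name string
#'
#' Trims, collapses internal whitespace and case-folds. All term and
#' drug-name matching in the pipeline (lexicon lookup, MedDRA map lookup,
#' label/IME/DME lists, cross-database overlap) goes through this one
#' normalization so that `"Diarrhoea "` and `"diarrhoea"` compare equal.
#' Matching is exact after normalization; there is no substring or fuzzy
#' matching, which avoids false positives from combination-product names.
#'
#' @param x character vector.
#' @return normalized character vector (lower case).
#' @export
normalize_term <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Load a one-term-per-line list file
#'
#' Used for the drug-name lexicon, the label-term list and the IME/DME
#' lists. Blank lines and lines starting with `#` are ignored; terms are
#' normalized with [normalize_term()].
#'
#' @param path file path.
#' @return character vector of normalized terms.
#' @export
load_term_list <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(normalize_term(x))
}

#' Load a preferred-term to system-organ-class mapping table
#'
#' A stand-in for the licensed MedDRA dictionary: a two-column TSV with
#' header `pt<TAB>soc`. Each preferred term must map to exactly one SOC.
#'
#' @param path TSV path.
#' @param version optional version label stored as an attribute.
#' @return `data.table` with normalized `pt` and `soc` columns.
#' @export
load_meddra_map <- function(path, version = NA_character_) {
  stopifnot(file.exists(path))
  m <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                         encoding = "UTF-8")
  if (!all(c("pt", "soc") %in% names(m))) {
    stop("PT->SOC map must have columns 'pt' and 'soc': ", path)
  }
  m[, pt := normalize_term(pt)]
  m <- unique(m, by = "pt")
  stopifnot(anyDuplicated(m$pt) == 0)
  attr(m, "version") <- version
  m[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
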