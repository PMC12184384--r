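# FAERS quarterly ASCII extracts: "$"-delimited text, one header line per
# file, files DEMO/DRUG/REAC/THER/OUTC/INDI plus a deleted-case list (one
# CASEID per line). No installed reader handles this dialect, so lines are
# split explicitly; rows whose field count disagrees with the header are
# counted as malformed and skipped, never fatal.

read_dollar_file <- function(path, required = character()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- toupper(trimws(strsplit(lines[1], "$", fixed = TRUE)[[1]]))
  miss <- setdiff(required, header)
  if (length(miss)) {
    stop(sprintf("file %s is missing mandatory column(s): %s",
                 basename(path), paste(miss, collapse = ", ")))
  }
  body <- lines[-1]
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # a trailing empty field is dropped by strsplit; tolerate one short field
  ok <- nf == length(header) | nf == length(header) - 1L
  malformed <- sum(!ok)
  parts <- parts[ok]
  if (length(parts)) {
    mat <- t(vapply(parts, function(p) {
      length(p) <- length(header)
      p
    }, character(length(header))))
    dt <- data.table::as.data.table(mat)
    data.table::setnames(dt, header)
    dt[is.na(dt)] <- ""
  } else {
    dt <- data.table::setnames(
      data.table::as.data.table(matrix(character(0), 0, length(header))), header)
  }
  attr(dt, "malformed") <- malformed
  dt
}

find_faers_file <- function(dir, stem) {
  hits <- list.files(dir, pattern = paste0("(?i)^", stem, ".*\\.txt$"),
                     full.names = TRUE)
  if (length(hits) == 0L) return(NULL)
  sort(hits)[1]
}

#' Read one FAERS-dialect quarterly file set
#'
#' Reads the `$`-delimited DEMO, DRUG, REAC, THER, OUTC and INDI tables from
#' a directory (files matched case-insensitively by stem, e.g. `DEMO24Q1.txt`)
#' together with an optional deleted-case list (`DELETED*.txt`, one CASEID
#' per line). Column values are kept as character; unknown extra columns are
#' preserved. Malformed rows (wrong field count) are counted per file and
#' reported in the `malformed` attribute, not fatal. A DEMO file without
#' PRIMARYID or CASEID is a hard error.
#'
#' @param dir directory containing the quarter's files.
#' @return a list of `data.table`s `demo`, `drug`, `reac`, `ther`, `outc`,
#'   `indi` (missing optional files yield `NULL`), `deleted` (character
#'   vector of case ids) and a named integer vector attribute `malformed`.
#' @export
parse_faers_quarter <- function(dir) {
  stopifnot(dir.exists(dir))
  demo_path <- find_faers_file(dir, "demo")
  if (is.null(demo_path)) stop("no DEMO*.txt found in ", dir)
  out <- list()
  malformed <- integer()
  req <- list(demo = c("PRIMARYID", "CASEID"),
              drug = c("PRIMARYID", "DRUGNAME", "ROLE_COD"),
              reac = c("PRIMARYID", "PT"),
              ther = c("PRIMARYID", "START_DT"),
              outc = c("PRIMARYID", "OUTC_COD"),
              indi = c("PRIMARYID", "INDI_PT"))
  for (stem in names(req)) {
    path <- find_faers_file(dir, stem)
    if (is.null(path)) {
      if (stem == "demo") stop("no DEMO*.txt found in ", dir)
      out[[stem]] <- NULL
      next
    }
    dt <- read_dollar_file(path, required = req[[stem]])
    malformed[stem] <- attr(dt, "malformed")
    out[[stem]] <- dt
  }
  del_path <- list.files(dir, pattern = "(?i)^delet.*\\.txt$", full.names = TRUE)
  out$deleted <- if (length(del_path)) {
    x <- trimws(readLines(del_path[1], warn = FALSE))
    x[nzchar(x)]
  } else character(0)
  attr(out, "malformed") <- malformed
  out
}
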