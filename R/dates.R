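#' Parse partial date tokens
#'
#' Spontaneous-report databases carry dates as compact tokens whose length
#' encodes their precision: `"YYYYMMDD"` (day), `"YYYYMM"` (month) or
#' `"YYYY"` (year). Slash-separated variants (`"2020/03/15"`, `"2020/03"`)
#' are accepted as the JADER-style spelling. Precision is preserved rather
#' than imputed: only day-precision tokens yield a `Date`, because
#' time-to-onset analysis excludes imprecise dates.
#'
#' @param x character vector of raw tokens (`NA` and `""` allowed).
#' @return a `data.table` with columns `token`, `year`, `month`, `day`
#'   (integer or `NA`), `precision` (`"day"`, `"month"`, `"year"` or
#'   `"none"`) and `date` (`Date`, `NA` unless day precision).
#' @examples
#' parse_date_token(c("20240315", "202401", "2024", "", "2020/05/07"))
#' @export
parse_date_token <- function(x) {
  x <- as.character(x)
  tok <- gsub("/", "", trimws(x))
  tok[is.na(tok)] <- ""
  n <- length(tok)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep("none", n)

  is_day <- grepl("^[0-9]{8}$", tok)
  is_month <- grepl("^[0-9]{6}$", tok)
  is_year <- grepl("^[0-9]{4}$", tok)

  year[is_year] <- as.integer(tok[is_year])
  precision[is_year] <- "year"
  year[is_month] <- as.integer(substr(tok[is_month], 1, 4))
  month[is_month] <- as.integer(substr(tok[is_month], 5, 6))
  precision[is_month] <- "month"
  year[is_day] <- as.integer(substr(tok[is_day], 1, 4))
  month[is_day] <- as.integer(substr(tok[is_day], 5, 6))
  day[is_day] <- as.integer(substr(tok[is_day], 7, 8))
  precision[is_day] <- "day"

  # reject impossible calendar components (e.g. month 13, Feb 30)
  date <- rep(as.Date(NA), n)
  if (any(is_day)) {
    d <- as.Date(sprintf("%04d-%02d-%02d", year[is_day], month[is_day], day[is_day]),
                 format = "%Y-%m-%d")
    date[is_day] <- d
    bad <- is.na(d)
    if (any(bad)) {
      idx <- which(is_day)[bad]
      precision[idx] <- "none"
      year[idx] <- month[idx] <- day[idx] <- NA_integer_
    }
  }
  bad_month <- is_month & (month < 1L | month > 12L)
  if (any(bad_month, na.rm = TRUE)) {
    idx <- which(bad_month)
    precision[idx] <- "none"
    year[idx] <- month[idx] <- NA_integer_
  }

  data.table::data.table(token = x, year = year, month = month, day = day,
                         precision = precision, date = date)
}

#' @keywords internal
#' @noRd
date_precision <- function(x) parse_date_token(x)$precision

# Day-precision Date or NA; vectorised.
token_date <- function(x) parse_date_token(x)$date

# Numeric sort key for FDA receipt dates: missing sorts as -Inf so any dated
# version of a case wins during deduplication.
receipt_sort_key <- function(token) {
  p <- parse_date_token(token)
  key <- rep(-Inf, nrow(p))
  ok <- p$precision != "none"
  key[ok] <- p$year[ok] * 10000 +
    ifelse(is.na(p$month[ok]), 0, p$month[ok]) * 100 +
    ifelse(is.na(p$day[ok]), 0, p$day[ok])
  key
}
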