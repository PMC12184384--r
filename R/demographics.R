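#' Demographic and outcome summary of a report collection
#'
#' Tabulates retained reports by sex, age band, weight band, reporting
#' country (top `k`), outcome code and indication (top `k`), each with a
#' percentage. Age bands follow the convention of the source database:
#' 18-65 / >65 years for FAERS, 20-70 / >70 years for JADER. Percentage
#' denominators: the retained report count for demographics, countries and
#' indications in both databases and for FAERS outcome codes (a report can
#' carry several outcomes, so FAERS outcome percentages need not sum to
#' 100); JADER outcomes are recorded per reaction entry, so their
#' denominator is the outcome-entry total.
#'
#' @param reports a `safety_reports` object.
#' @param top_k how many countries/indications to list.
#' @return `data.table` with columns `section`, `category`, `n`, `pct`
#'   (percent, 1 decimal) and `denominator`.
#' @export
summarize_demographics <- function(reports, top_k = 5L) {
  d <- reports$demo
  n <- nrow(d)
  src <- attr(reports, "source_db")
  out <- list()
  add <- function(section, category, count, denom) {
    out[[length(out) + 1]] <<- data.table::data.table(
      section = section, category = category, n = as.integer(count),
      pct = round(100 * count / denom, 1), denominator = as.integer(denom))
  }

  sex_lab <- c(F = "Female", M = "Male", U = "Unknown")
  for (s in names(sex_lab)) add("sex", sex_lab[[s]], sum(d$sex == s), n)

  age <- d$age_years
  if (src == "FAERS") {
    bands <- list("<18 years" = !is.na(age) & age < 18,
                  "18-65 years" = !is.na(age) & age >= 18 & age <= 65,
                  ">65 years" = !is.na(age) & age > 65,
                  "Unknown" = is.na(age))
  } else {
    bands <- list("<20 years" = !is.na(age) & age < 20,
                  "20-70 years" = !is.na(age) & age >= 20 & age < 70,
                  ">70 years" = !is.na(age) & age >= 70,
                  "Unknown" = is.na(age))
  }
  for (b in names(bands)) add("age", b, sum(bands[[b]]), n)

  w <- d$weight_kg
  wb <- list("<50 kg" = !is.na(w) & w < 50,
             "50-100 kg" = !is.na(w) & w >= 50 & w <= 100,
             ">100 kg" = !is.na(w) & w > 100,
             "Unknown" = is.na(w))
  for (b in names(wb)) add("weight", b, sum(wb[[b]]), n)

  ctry <- d$reporter_country
  ctry[is.na(ctry) | !nzchar(ctry)] <- "Unknown"
  tc <- sort(table(ctry), decreasing = TRUE)
  tc <- tc[setdiff(names(tc), "Unknown")]
  for (cn in utils::head(names(tc), top_k)) add("country", cn, tc[[cn]], n)

  oc <- reports$outcomes[nzchar(trimws(code))]
  outcome_denom <- if (src == "JADER") nrow(reports$outcomes) else n
  if (nrow(oc)) {
    to <- sort(table(oc$code), decreasing = TRUE)
    for (cn in names(to)) add("outcome", cn, to[[cn]], outcome_denom)
  }

  ind <- reports$indications[nzchar(term)]
  if (nrow(ind)) {
    ti <- sort(table(ind$term), decreasing = TRUE)
    for (cn in utils::head(names(ti), top_k)) add("indication", cn, ti[[cn]], n)
  }

  data.table::rbindlist(out)
}

#' Annual distribution of reports
#'
#' Counts retained reports per receipt year, restricted to a study window.
#' Years outside the window are dropped with a warning.
#'
#' @param reports a `safety_reports` object.
#' @param window integer vector `c(first_year, last_year)`; `NULL` keeps all.
#' @return `data.table` with columns `year`, `n`.
#' @export
annual_counts <- function(reports, window = c(2004L, 2024L)) {
  yr <- reports$demo$receipt_year
  yr <- yr[!is.na(yr)]
  if (length(yr) == 0L) {
    return(data.table::data.table(year = integer(), n = integer()))
  }
  if (!is.null(window)) {
    out_of_window <- yr < window[1] | yr > window[2]
    if (any(out_of_window)) {
      warning(sum(out_of_window), " report(s) outside the study window excluded")
      yr <- yr[!out_of_window]
    }
  }
  tab <- table(yr)
  data.table::data.table(year = as.integer(names(tab)), n = as.integer(tab))
}
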