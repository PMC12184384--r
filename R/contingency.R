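#' Count drug-event pairs at the PT or SOC level
#'
#' The counting unit is the drug-event pair: each distinct term in a report
#' contributes one count, so a report listing k distinct preferred terms
#' adds k to the drug's event total, and a term repeated within one report
#' is counted once. At SOC level a report contributes one count per distinct
#' SOC it touches.
#'
#' @param reports a `safety_reports` object with SOC-coded events.
#' @param level `"pt"` or `"soc"`.
#' @return `data.table` with columns `term`, `n`, sorted by decreasing `n`.
#' @export
event_counts <- function(reports, level = c("pt", "soc")) {
  level <- match.arg(level)
  ev <- unique(reports$events[, .(report_id, term = get(level))])
  ev <- ev[!is.na(term) & nzchar(term)]
  out <- ev[, .(n = .N), by = term]
  data.table::setorder(out, -n, term)
  out[]
}

#' Build 2x2 disproportionality tables
#'
#' For every term observed with the target drug, forms the classical
#' contingency table against the database background:
#' `a` reports pairing the target drug with the term, `b` the target drug
#' with any other term, `c` other drugs with the term, `d` other drugs with
#' other terms. The background multiset must cover the full database
#' (target drug included); terms never observed with the target drug
#' (`a = 0`) are not emitted since no estimator is defined there. Tables
#' with a zero margin are flagged `degenerate` and excluded from estimation
#' downstream.
#'
#' @param target `data.table(term, n)` of the target drug's event counts
#'   (see [event_counts()]).
#' @param background `data.table(term, n)` for the whole database at the
#'   same level.
#' @param level label stored on the result (`"pt"` or `"soc"`).
#' @return `data.table` with columns `term`, `level`, `a`, `b`, `c`, `d`,
#'   `n_total`, `degenerate`.
#' @export
build_tables <- function(target, background, level = c("pt", "soc")) {
  level <- match.arg(level)
  target <- data.table::as.data.table(target)
  background <- data.table::as.data.table(background)
  if (nrow(target) == 0L) stop("target event multiset is empty")
  stopifnot(all(c("term", "n") %in% names(target)),
            all(c("term", "n") %in% names(background)))
  bg <- background[, .(n_bg = sum(n)), by = term]
  tt <- target[, .(a = sum(n)), by = term]
  merged <- bg[tt, on = "term"]
  if (any(is.na(merged$n_bg)) ||
      any(merged$a > merged$n_bg)) {
    stop("background multiset does not cover the target multiset")
  }
  target_total <- sum(tt$a)
  grand_total <- sum(bg$n_bg)
  out <- merged[, .(
    term,
    level = level,
    a = as.numeric(a),
    b = as.numeric(target_total - a),
    c = as.numeric(n_bg - a),
    d = as.numeric((grand_total - n_bg) - (target_total - a))
  )]
  out[, n_total := a + b + c + d]
  out[, degenerate := (a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0]
  data.table::setorder(out, -a, term)
  out[]
}

#' Reporting rate of one term
#'
#' The share of a term among all of the drug's reported events,
#' `100 * a / total`, the percentage printed next to case counts in
#' top-term rankings.
#'
#' @param a term count.
#' @param total the drug's total event count at the same level.
#' @param digits decimals to round to (2 for PT shares, 1 for demographic
#'   shares).
#' @return percentage (numeric).
#' @export
reporting_rate <- function(a, total, digits = 2) {
  if (any(total <= 0)) stop("total must be positive")
  stopifnot(all(a >= 0), all(a <= total))
  round(100 * a / total, digits)
}
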