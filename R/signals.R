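#' Combine algorithm flags into positive signals
#'
#' A term is a positive signal only when the ROR, PRR, BCPNN and MGPS
#' criteria are met simultaneously — the strictest intersection rule, which
#' trades sensitivity for a low false-positive rate.
#'
#' @param flag_ror,flag_prr,flag_bcpnn,flag_mgps logical vectors.
#' @return logical vector, `TRUE` where all four flags are `TRUE`.
#' @export
intersect_signals <- function(flag_ror, flag_prr, flag_bcpnn, flag_mgps) {
  isT <- function(x) !is.na(x) & x
  isT(flag_ror) & isT(flag_prr) & isT(flag_bcpnn) & isT(flag_mgps)
}

#' Flag unexpected signals
#'
#' A positive signal is unexpected when its preferred term is not listed on
#' the drug label. Non-positive terms are never flagged.
#'
#' @param metrics table with columns `term` and `positive`.
#' @param label_terms character vector of label-listed preferred terms.
#' @return the table with a logical `unexpected` column added.
#' @export
flag_unexpected <- function(metrics, label_terms) {
  metrics <- data.table::as.data.table(metrics)
  label_terms <- normalize_term(label_terms)
  label_terms <- label_terms[nzchar(label_terms)]
  if (length(label_terms) == 0L) {
    warning("label-term list is empty: every positive signal is unexpected")
  }
  metrics[, unexpected := positive & !normalize_term(term) %in% label_terms]
  metrics[]
}

#' Overlap between two databases' positive-signal sets
#'
#' @param terms_a,terms_b character vectors of positive-signal terms at the
#'   same level (normalized internally).
#' @return list with `overlap`, `a_only`, `b_only` (sorted character
#'   vectors) and the three counts.
#' @export
cross_database_overlap <- function(terms_a, terms_b) {
  a <- unique(normalize_term(terms_a))
  b <- unique(normalize_term(terms_b))
  list(overlap = sort(intersect(a, b)),
       a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       n_overlap = length(intersect(a, b)),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)))
}

#' Clinical priority score for positive signals
#'
#' Scores each signal 0-2 on four criteria and sums them to 0-8:
#' \itemize{
#'   \item reporting rate (share of the drug's events): >10% = 2,
#'     1-10% = 1, <1% = 0 — the very common / common / uncommon convention;
#'   \item signal stability (number of the four algorithms whose flag is
#'     true): >=3 = 2, exactly 2 = 1, otherwise 0;
#'   \item reported case fatality (share of reports with the term that
#'     recorded death): >50% = 2, 25-50% = 1, <25% = 0 — the high bar
#'     reflects background mortality in oncology reporting;
#'   \item clinical relevance: designated medical event = 2, important
#'     medical event = 1, else 0 (a term on both lists scores as DME).
#' }
#' Totals 0-2, 3-5 and 6-8 map to low, medium and high clinical priority.
#'
#' @param term character vector of signal terms.
#' @param reporting_rate_pct percent share of the drug's events (vector).
#' @param n_algorithms number of algorithms flagging the term (0-4).
#' @param fatality_frac fraction (0-1) of reports with the term whose
#'   outcome is death.
#' @param ime_terms,dme_terms character vectors (normalized internally).
#' @return `data.table` with the four criterion scores, `total` and
#'   `category`.
#' @export
score_priority <- function(term, reporting_rate_pct, n_algorithms,
                           fatality_frac, ime_terms = character(),
                           dme_terms = character()) {
  ime <- normalize_term(ime_terms)
  dme <- normalize_term(dme_terms)
  tnorm <- normalize_term(term)

  rate_pts <- ifelse(reporting_rate_pct > 10, 2L,
                     ifelse(reporting_rate_pct >= 1, 1L, 0L))
  stab_pts <- ifelse(n_algorithms >= 3, 2L, ifelse(n_algorithms == 2, 1L, 0L))
  fatal_pts <- ifelse(fatality_frac > 0.5, 2L,
                      ifelse(fatality_frac >= 0.25, 1L, 0L))
  rel_pts <- ifelse(tnorm %in% dme, 2L, ifelse(tnorm %in% ime, 1L, 0L))

  total <- rate_pts + stab_pts + fatal_pts + rel_pts
  category <- cut(total, breaks = c(-1, 2, 5, 8),
                  labels = c("low", "medium", "high"))
  data.table::data.table(term = term,
                         rate_points = rate_pts,
                         stability_points = stab_pts,
                         fatality_points = fatal_pts,
                         relevance_points = rel_pts,
                         total = total,
                         category = as.character(category))
}

#' Fraction of a term's reports with a fatal outcome
#'
#' Death is identified by outcome code: `DE` in the FAERS dialect, the
#' death outcome term (死亡) in the JADER dialect. The denominator is the
#' number of reports containing the term.
#'
#' @param reports a `safety_reports` object.
#' @param terms preferred terms to evaluate.
#' @return `data.table(term, n_reports, n_death, fatality_frac)`.
#' @export
term_fatality <- function(reports, terms) {
  terms <- normalize_term(terms)
  src <- attr(reports, "source_db")
  death_ids <- if (src == "JADER") {
    unique(reports$outcomes[trimws(code) == jader_death_term, report_id])
  } else {
    unique(reports$outcomes[toupper(trimws(code)) == "DE", report_id])
  }
  ev <- unique(reports$events[pt %in% terms, .(report_id, pt)])
  out <- ev[, .(n_reports = .N, n_death = sum(report_id %in% death_ids)),
            by = .(term = pt)]
  out <- out[data.table::data.table(term = terms), on = "term"]
  out[is.na(n_reports), `:=`(n_reports = 0L, n_death = 0L)]
  out[, fatality_frac := ifelse(n_reports > 0, n_death / n_reports, 0)]
  out[]
}

#' Chi-squared comparison of two SOC composition vectors
#'
#' Pearson chi-squared test (no continuity correction) on the 2 x K table
#' of SOC-level event counts from two databases, on K-1 degrees of freedom.
#' SOCs absent from one cohort enter with a zero count; expected counts
#' come from the pooled margins.
#'
#' @param counts_a,counts_b named integer vectors of SOC counts.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
soc_composition_test <- function(counts_a, counts_b) {
  socs <- union(names(counts_a), names(counts_b))
  if (length(socs) < 2L) stop("need at least two SOC categories")
  m <- rbind(a = counts_a[socs], b = counts_b[socs])
  m[is.na(m)] <- 0
  m <- m[, colSums(m) > 0, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}
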