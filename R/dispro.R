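#' Default signal thresholds
#'
#' The standard per-algorithm positive-signal criteria used in FAERS
#' disproportionality studies: ROR requires at least 3 cases and a 95% CI
#' lower bound strictly above 1; PRR requires at least 3 cases, PRR >= 2
#' and chi-squared >= 4; BCPNN requires IC025 > 0; MGPS requires
#' EBGM05 > 2. Each is configurable.
#'
#' @return named list of threshold values.
#' @export
default_thresholds <- function() {
  list(min_cases = 3,
       ror_ci_low = 1,
       prr_min = 2,
       chi2_min = 4,
       ic025_min = 0,
       ebgm05_min = 2)
}

#' Evaluate the per-algorithm signal flags
#'
#' @param metrics `data.table` with columns `a`, `ror_low`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (as produced by [compute_disproportionality()]).
#' @param thresholds list from [default_thresholds()].
#' @return the input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps` and `positive` (all four true).
#' @export
evaluate_thresholds <- function(metrics, thresholds = default_thresholds()) {
  metrics <- data.table::as.data.table(metrics)
  th <- thresholds
  isT <- function(x) !is.na(x) & x
  metrics[, flag_ror := isT(a >= th$min_cases & ror_low > th$ror_ci_low)]
  metrics[, flag_prr := isT(a >= th$min_cases & prr >= th$prr_min &
                              chi2 >= th$chi2_min)]
  metrics[, flag_bcpnn := isT(ic025 > th$ic025_min)]
  metrics[, flag_mgps := isT(ebgm05 > th$ebgm05_min)]
  metrics[, n_flags := flag_ror + flag_prr + flag_bcpnn + flag_mgps]
  metrics[, positive := flag_ror & flag_prr & flag_bcpnn & flag_mgps]
  metrics[]
}

#' Compute all four disproportionality statistics for a table set
#'
#' Runs ROR (Woolf CI), PRR with Pearson chi-squared, the BCPNN information
#' component and MGPS EBGM on every non-degenerate contingency table, then
#' evaluates the per-algorithm thresholds. The MGPS prior should be fitted
#' on all drug-event cells of the database ([mgps_fit_prior()]); when
#' `prior = NULL` it is fitted on the supplied tables themselves.
#'
#' @param tables output of [build_tables()].
#' @param prior an `mgps_prior`, or `NULL` to fit from `tables`.
#' @param thresholds list from [default_thresholds()].
#' @return `data.table`: one row per non-degenerate table with the counts,
#'   all estimates, interval bounds, flags and `positive`.
#' @export
compute_disproportionality <- function(tables, prior = NULL,
                                       thresholds = default_thresholds()) {
  tab <- data.table::as.data.table(tables)
  if (!"degenerate" %in% names(tab)) tab[, degenerate := FALSE]
  tab <- tab[degenerate == FALSE]
  if (nrow(tab) == 0L) stop("no non-degenerate tables to score")
  E <- (tab$a + tab$b) * (tab$a + tab$c) / tab$n_total
  if (is.null(prior)) prior <- mgps_fit_prior(tab$a, E)
  out <- cbind(
    tab[, .(term, level, a, b, c, d)],
    ror_metrics(tab$a, tab$b, tab$c, tab$d),
    prr_metrics(tab$a, tab$b, tab$c, tab$d),
    bcpnn_metrics(tab$a, tab$b, tab$c, tab$d),
    mgps_ebgm(tab$a, E, prior)
  )
  out[, expected := E]
  evaluate_thresholds(out, thresholds)
}

#' Write a signal table as TSV
#'
#' Column layout mirrors the per-term signal tables of published
#' disproportionality analyses: term, level, the 2x2 counts, ROR with its
#' 95% CI, PRR and chi-squared, IC and IC025, EBGM and EBGM05, the four
#' flags and the combined positive indicator.
#'
#' @param metrics table from [compute_disproportionality()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(metrics, path) {
  cols <- intersect(
    c("term", "level", "a", "b", "c", "d", "ror", "ror_low", "ror_high",
      "prr", "chi2", "ic", "ic025", "ebgm", "ebgm05",
      "flag_ror", "flag_prr", "flag_bcpnn", "flag_mgps", "positive",
      "unexpected", "priority_total", "priority_category"),
    names(metrics))
  data.table::fwrite(data.table::as.data.table(metrics)[, cols, with = FALSE],
                     path, sep = "\t")
  invisible(path)
}
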