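# Frequentist disproportionality statistics on the 2x2 table
#   a = drug & event, b = drug & other events,
#   c = other drugs & event, d = other drugs & other events.

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' ROR = (a d)/(b c); the interval is
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). Tables with any zero
#' cell are returned as not estimable (`NA`) rather than continuity
#' corrected.
#'
#' @param a,b,c,d the 2x2 cell counts (vectorised).
#' @return `data.table` with columns `ror`, `ror_low`, `ror_high`.
#' @export
ror_metrics <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  low <- exp(log(est) - 1.96 * se)
  high <- exp(log(est) + 1.96 * se)
  bad <- a == 0 | b == 0 | c == 0 | d == 0
  est[bad] <- low[bad] <- high[bad] <- NA_real_
  data.table::data.table(ror = est, ror_low = low, ror_high = high)
}

#' Proportional reporting ratio and Pearson chi-squared
#'
#' PRR = (a/(a+b)) / (c/(c+d)); the chi-squared statistic is the
#' uncorrected Pearson shortcut
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 degree of freedom.
#' `c = 0` (or a zero margin) is flagged not estimable.
#'
#' @inheritParams ror_metrics
#' @return `data.table` with columns `prr`, `chi2`.
#' @export
prr_metrics <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  prr <- (a / (a + b)) / (c / (c + d))
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  bad <- c == 0 | (a + b) == 0 | (c + d) == 0
  prr[bad] <- NA_real_
  chi2[(a + b) == 0 | (c + d) == 0 | (a + c) == 0 | (b + d) == 0] <- NA_real_
  data.table::data.table(prr = prr, chi2 = chi2)
}
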