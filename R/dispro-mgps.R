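# Multi-item gamma Poisson shrinker (MGPS, DuMouchel 1999).
#
# Observed counts a_i for drug-event cells are modelled as
#   a_i ~ Poisson(lambda_i * E_i),  E_i = (a+b)(a+c)/N the independence
# expectation, with the relative reporting ratio lambda_i drawn from a
# two-component gamma mixture prior
#   lambda ~ P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2).
# Marginally each a_i is a mixture of negative binomials, which gives a
# closed-form likelihood for empirical-Bayes estimation of the five
# hyperparameters. The posterior of lambda given a is again a mixture of
# gammas, from which EBGM (posterior geometric mean) and EBGM05 (5th
# posterior percentile) follow.

mgps_loglik <- function(theta, a, E) {
  p <- stats::plogis(theta[1])
  a1 <- exp(theta[2]); b1 <- exp(theta[3])
  a2 <- exp(theta[4]); b2 <- exp(theta[5])
  l1 <- stats::dnbinom(a, size = a1, mu = a1 * E / b1, log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, mu = a2 * E / b2, log = TRUE)
  m <- pmax(l1 + log(p), l2 + log1p(-p))
  ll <- m + log(exp(l1 + log(p) - m) + exp(l2 + log1p(-p) - m))
  sum(ll)
}

#' Fit the MGPS gamma-mixture prior by marginal maximum likelihood
#'
#' Maximizes the negative-binomial mixture marginal likelihood of all
#' drug-event cell counts of a database (not only the target drug's cells)
#' over the five DuMouchel hyperparameters, by quasi-Newton (BFGS) search
#' on an unconstrained transform (logit mixture weight, log shapes/rates)
#' from several starting points: the classical DuMouchel start
#' `(P = 1/3, alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4)`, a flat
#' start at the independence prior, and seed-controlled random
#' perturbations.
#'
#' @param a integer vector of observed cell counts.
#' @param E expected counts `(a+b)(a+c)/N` per cell, same length.
#' @param n_random extra random starts.
#' @param seed seed for the random starts (deterministic fit).
#' @return an object of class `mgps_prior`: list with `P`, `alpha1`,
#'   `beta1`, `alpha2`, `beta2`, `loglik`, `converged`, `n_cells`.
#' @references DuMouchel W (1999) Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53(3):177-190.
#' @export
mgps_fit_prior <- function(a, E, n_random = 3L, seed = 1L) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < 2L) stop("need at least two cells to fit the prior")
  starts <- list(
    c(stats::qlogis(1 / 3), log(0.2), log(0.1), log(2), log(4)),
    c(0, 0, 0, log(2), log(2)),
    c(stats::qlogis(0.1), log(1), log(1), log(5), log(1))
  )
  if (n_random > 0) {
    # seeded random starts drawn without disturbing the caller's RNG stream
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    set.seed(seed)
    starts <- c(starts, lapply(seq_len(n_random),
                               function(i) stats::rnorm(5, 0, 1.5)))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, function(th) {
        # extreme parameter proposals during line search can overflow the
        # negative-binomial density; treat them as -Inf likelihood
        ll <- suppressWarnings(mgps_loglik(th, a, E))
        if (!is.finite(ll)) 1e12 else -ll
      }, method = "BFGS", control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("MGPS prior fit failed from every start")
  th <- best$par
  prior <- structure(list(
    P = stats::plogis(th[1]),
    alpha1 = exp(th[2]), beta1 = exp(th[3]),
    alpha2 = exp(th[4]), beta2 = exp(th[5]),
    loglik = -best$value,
    converged = any_conv,
    n_cells = length(a)
  ), class = "mgps_prior")
  if (!any_conv) {
    stop("MGPS prior fit did not converge; best log-likelihood ",
         signif(prior$loglik, 8))
  }
  prior
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(paste0("<mgps_prior> P=%.3f Gamma(%.3g, %.3g) + (1-P) ",
                     "Gamma(%.3g, %.3g); loglik %.2f on %d cells\n"),
              x$P, x$alpha1, x$beta1, x$alpha2, x$beta2, x$loglik, x$n_cells))
  invisible(x)
}

# Posterior mixture weights Q, shapes and rates for lambda | a.
mgps_posterior <- function(a, E, prior) {
  l1 <- stats::dnbinom(a, size = prior$alpha1, mu = prior$alpha1 * E / prior$beta1,
                       log = TRUE) + log(prior$P)
  l2 <- stats::dnbinom(a, size = prior$alpha2, mu = prior$alpha2 * E / prior$beta2,
                       log = TRUE) + log1p(-prior$P)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q1 = q1,
       s1 = prior$alpha1 + a, r1 = prior$beta1 + E,
       s2 = prior$alpha2 + a, r2 = prior$beta2 + E)
}

#' Empirical Bayes geometric mean and its 5th percentile
#'
#' Given the fitted prior, the posterior of the relative reporting ratio is
#' a two-component gamma mixture with updated shapes `alpha_k + a` and
#' rates `beta_k + E`. `EBGM = 2^E(log2 lambda | a)` (the posterior
#' geometric mean) and `EBGM05` is the 5th percentile of the posterior,
#' found by bisection on the mixture CDF to 1e-8 relative tolerance.
#'
#' @param a observed counts (vector).
#' @param E expected counts (vector).
#' @param prior an `mgps_prior` object.
#' @return `data.table` with columns `ebgm`, `ebgm05`.
#' @export
mgps_ebgm <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (any(E <= 0)) stop("E must be positive (degenerate tables are not estimable)")
  po <- mgps_posterior(a, E, prior)
  mean_log <- po$q1 * (digamma(po$s1) - log(po$r1)) +
    (1 - po$q1) * (digamma(po$s2) - log(po$r2))
  ebgm <- exp(mean_log)

  ebgm05 <- vapply(seq_along(a), function(i) {
    cdf <- function(x) {
      po$q1[i] * stats::pgamma(x, po$s1[i], rate = po$r1[i]) +
        (1 - po$q1[i]) * stats::pgamma(x, po$s2[i], rate = po$r2[i]) - 0.05
    }
    lo <- min(stats::qgamma(0.001, po$s1[i], rate = po$r1[i]),
              stats::qgamma(0.001, po$s2[i], rate = po$r2[i]))
    hi <- max(stats::qgamma(0.999, po$s1[i], rate = po$r1[i]),
              stats::qgamma(0.999, po$s2[i], rate = po$r2[i]))
    stats::uniroot(cdf, lower = lo, upper = hi, extendInt = "upX",
                   tol = 1e-8 * max(1, hi))$root
  }, numeric(1))
  data.table::data.table(ebgm = ebgm, ebgm05 = ebgm05)
}
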