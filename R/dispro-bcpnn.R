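#' BCPNN information component (closed form)
#'
#' The information component of the Bayesian confidence propagation neural
#' network measures log2 of the observed-to-expected reporting ratio under
#' independent Dirichlet priors on the cell, row and column probabilities.
#' This is the closed-form posterior approximation of Bate et al. (1998)
#' with the standard hyperparameters `alpha = beta = 2`,
#' `alpha1 = beta1 = 1`, `gamma11 = 1` and
#' `gamma = gamma11 (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`, chosen
#' so the prior is centred on independence (IC = 0 for an empty database).
#' The lower signal bound is `IC025 = E(IC) - 2 sqrt(V(IC))`. The priors
#' regularize zero cells, so every table is estimable.
#'
#' @inheritParams ror_metrics
#' @return `data.table` with columns `ic` (the posterior expectation
#'   `E(IC)`), `ic025`.
#' @export
bcpnn_metrics <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  alpha <- 2; beta <- 2
  alpha1 <- 1; beta1 <- 1
  gamma11 <- 1
  gamma <- gamma11 * (n + alpha) * (n + beta) /
    ((a + b + alpha1) * (a + c + beta1))

  e_ic <- log2((a + gamma11) * (n + alpha) * (n + beta) /
                 ((n + gamma) * (a + b + alpha1) * (a + c + beta1)))
  v_ic <- ((n - a + gamma - gamma11) / ((a + gamma11) * (1 + n + gamma)) +
             (n - a - b + alpha - alpha1) / ((a + b + alpha1) * (1 + n + alpha)) +
             (n - a - c + beta - beta1) / ((a + c + beta1) * (1 + n + beta))) /
    log(2)^2
  data.table::data.table(ic = e_ic, ic025 = e_ic - 2 * sqrt(v_ic))
}
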