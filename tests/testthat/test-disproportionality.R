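test_that("ROR matches direct arithmetic and scales correctly", {
  # symmetric table: no disproportionality
  r <- ror_metrics(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_true(r$ror_low < 1 && r$ror_high > 1)

  # frozen oracle values computed by direct arithmetic in an independent
  # script: ROR = (10*9900)/(90*100) = 11;
  # se = sqrt(1/10 + 1/90 + 1/100 + 1/9900) = 0.34815531;
  # CI = exp(log(11) -/+ 1.96*se)
  r <- ror_metrics(10, 90, 100, 9900)
  expect_equal(r$ror, 11)
  expect_equal(r$ror_low, 5.5595149, tolerance = 1e-7)
  expect_equal(r$ror_high, 21.7644887, tolerance = 1e-7)

  # doubling all cells keeps the estimate, narrows the interval
  r2 <- ror_metrics(20, 180, 200, 19800)
  expect_equal(r2$ror, r$ror)
  expect_lt(r$ror_low, r2$ror_low)
  expect_gt(r$ror_high, r2$ror_high)

  # zero cells are not estimable
  expect_true(is.na(ror_metrics(0, 10, 10, 10)$ror))
})

test_that("PRR and chi-squared match the expansion oracle", {
  p <- prr_metrics(10, 10, 10, 10)
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  # PRR = (10/100)/(100/10000) = 10; chi2 from the full (O-E)^2/E expansion
  p <- prr_metrics(10, 90, 100, 9900)
  expect_equal(p$prr, 10)
  expect_equal(p$chi2, chi2_expansion(10, 90, 100, 9900), tolerance = 1e-12)

  # independence (ad = bc) gives exactly zero
  expect_equal(prr_metrics(5, 10, 50, 100)$chi2, 0)
  expect_true(is.na(prr_metrics(3, 7, 0, 100)$prr))
})

test_that("chi-squared shortcut equals the expansion on 1000 random tables", {
  tabs <- random_tables(1000, seed = 99)
  got <- prr_metrics(tabs$a, tabs$b, tabs$c, tabs$d)$chi2
  expect_equal(got, chi2_expansion(tabs$a, tabs$b, tabs$c, tabs$d),
               tolerance = 1e-9)
})

test_that("information component shrinks toward the observed log2 ratio", {
  # independence in the large-N limit: a at its expectation gives IC near 0
  b <- bcpnn_metrics(100, 900, 900, 8100)   # a = (a+b)(a+c)/N exactly
  expect_equal(b$ic, 0, tolerance = 0.02)

  # step-by-step scalar evaluation of the closed-form posterior, written
  # out independently of the vectorised implementation
  a <- 10; bb <- 90; cc <- 100; d <- 9900
  n <- a + bb + cc + d
  g <- 1 * (n + 2) * (n + 2) / ((a + bb + 1) * (a + cc + 1))
  e_ic <- log2((a + 1) * (n + 2) * (n + 2) / ((n + g) * (a + bb + 1) * (a + cc + 1)))
  v_ic <- ((n - a + g - 1) / ((a + 1) * (1 + n + g)) +
             (n - a - bb + 2 - 1) / ((a + bb + 1) * (1 + n + 2)) +
             (n - a - cc + 2 - 1) / ((a + cc + 1) * (1 + n + 2))) / log(2)^2
  got <- bcpnn_metrics(a, bb, cc, d)
  expect_equal(got$ic, e_ic, tolerance = 1e-12)
  expect_equal(got$ic025, e_ic - 2 * sqrt(v_ic), tolerance = 1e-12)
  # shrinkage pulls the IC below the raw log2 observed/expected ratio
  expect_lt(got$ic, log2(a * n / ((a + bb) * (a + cc))))
  expect_gt(got$ic, 0.7 * log2(a * n / ((a + bb) * (a + cc))))

  # IC025 sits strictly below IC whenever the variance is positive
  tabs <- random_tables(200, seed = 3)
  bc <- bcpnn_metrics(tabs$a, tabs$b, tabs$c, tabs$d)
  expect_true(all(bc$ic025 < bc$ic))
})

test_that("scaling all cells sends IC and EBGM to the relative ratio", {
  a <- 12; b <- 88; cc <- 150; d <- 9750
  rrr <- a * (a + b + cc + d) / ((a + b) * (a + cc))
  ks <- c(1, 10, 100, 1000)
  ics <- vapply(ks, function(k) bcpnn_metrics(a * k, b * k, cc * k, d * k)$ic,
                numeric(1))
  expect_lt(abs(ics[4] - log2(rrr)), 1e-3)
  expect_true(all(diff(abs(ics - log2(rrr))) < 0))

  prior <- structure(list(P = 0.5, alpha1 = 1, beta1 = 1, alpha2 = 2,
                          beta2 = 2, loglik = 0, converged = TRUE,
                          n_cells = 0L), class = "mgps_prior")
  eb <- vapply(ks, function(k) {
    E <- (a + b) * (a + cc) / (a + b + cc + d) * k
    mgps_ebgm(a * k, E, prior)$ebgm
  }, numeric(1))
  expect_lt(abs(eb[4] - rrr) / rrr, 1e-2)
})

test_that("EBGM matches numerical posterior integration", {
  prior <- structure(list(P = 0.3, alpha1 = 0.6, beta1 = 0.4, alpha2 = 2.5,
                          beta2 = 2.1, loglik = 0, converged = TRUE,
                          n_cells = 0L), class = "mgps_prior")
  # shrinkage to the prior with no data; a/E recovery with much data
  eb0 <- mgps_ebgm(0, 0.01, prior)
  prior_gm <- exp(prior$P * (digamma(prior$alpha1) - log(prior$beta1)) +
                    (1 - prior$P) * (digamma(prior$alpha2) - log(prior$beta2)))
  expect_equal(eb0$ebgm, prior_gm, tolerance = 0.05)
  eb1 <- mgps_ebgm(100, 10, prior)
  expect_true(eb1$ebgm > 1 && eb1$ebgm < 10)
  eb2 <- mgps_ebgm(10000, 1000, prior)
  expect_gt(eb2$ebgm, 9.5)

  set.seed(21)
  cases <- data.table(a = sample(0:60, 40, TRUE),
                      E = stats::runif(40, 0.05, 30))
  got <- mgps_ebgm(cases$a, cases$E, prior)
  for (i in seq_len(nrow(cases))) {
    num <- ebgm_numeric(cases$a[i], cases$E[i], prior)
    expect_equal(got$ebgm[i], num$ebgm, tolerance = 1e-6)
    expect_equal(got$ebgm05[i], num$ebgm05, tolerance = 1e-6)
  }
  expect_true(all(got$ebgm05 < got$ebgm))
})

test_that("the prior fit recovers planted gamma-mixture structure", {
  set.seed(77)
  n <- 5000
  E <- stats::runif(n, 0.5, 20)
  # all-null database: every true lambda is 1
  a_null <- stats::rpois(n, E)
  pr <- mgps_fit_prior(a_null, E, n_random = 1L)
  prior_mean <- pr$P * pr$alpha1 / pr$beta1 + (1 - pr$P) * pr$alpha2 / pr$beta2
  expect_gt(prior_mean, 0.8)
  expect_lt(prior_mean, 1.25)

  # 10% of cells at lambda = 5: one component must sit near 5
  lam <- ifelse(stats::runif(n) < 0.1, 5, 1)
  a_mix <- stats::rpois(n, lam * E)
  pr2 <- mgps_fit_prior(a_mix, E, n_random = 1L)
  means <- c(pr2$alpha1 / pr2$beta1, pr2$alpha2 / pr2$beta2)
  expect_true(any(abs(means - 5) < 1))
  expect_true(any(abs(means - 1) < 0.3))

  # duplicating the data leaves the optimum unchanged
  pr3 <- mgps_fit_prior(c(a_null, a_null), c(E, E), n_random = 0L)
  prior_mean3 <- pr3$P * pr3$alpha1 / pr3$beta1 + (1 - pr3$P) * pr3$alpha2 / pr3$beta2
  expect_equal(prior_mean3, prior_mean, tolerance = 0.05)
})

test_that("threshold flags follow the rule table", {
  m <- data.table(
    a =        c(2,    10,   10,  50),
    ror_low =  c(50,   1.0,  2,   3),
    prr =      c(30,   3,    1.5, 6),
    chi2 =     c(100,  10,   3,   200),
    ic025 =    c(2,    -0.1, 0.5, 1.5),
    ebgm05 =   c(8,    1.9,  2.5, 4))
  f <- evaluate_thresholds(m)
  expect_equal(f$flag_ror, c(FALSE, FALSE, TRUE, TRUE))  # case floor; CI low = 1 exactly
  expect_equal(f$flag_prr, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(f$flag_bcpnn, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(f$flag_mgps, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(f$positive, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("all four estimators increase in a and agree in sign", {
  b <- 200; cc <- 300; d <- 20000
  prior <- structure(list(P = 0.4, alpha1 = 1, beta1 = 1, alpha2 = 2,
                          beta2 = 2, loglik = 0, converged = TRUE,
                          n_cells = 0L), class = "mgps_prior")
  avals <- c(5, 10, 20, 40, 80)
  ror <- ror_metrics(avals, b, cc, d)$ror
  prr <- prr_metrics(avals, b, cc, d)$prr
  ic <- bcpnn_metrics(avals, b, cc, d)$ic
  E <- (avals + b) * (avals + cc) / (avals + b + cc + d)
  eb <- mgps_ebgm(avals, E, prior)$ebgm
  expect_true(all(diff(ror) > 0) && all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0) && all(diff(eb) > 0))

  tabs <- random_tables(300, seed = 12)
  above <- with(tabs, a / (a + b) > c / (c + d))
  expect_equal(with(tabs, ror_metrics(a, b, c, d)$ror > 1), above)
  expect_equal(with(tabs, prr_metrics(a, b, c, d)$prr > 1), above)
})
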