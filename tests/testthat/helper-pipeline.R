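library(data.table)

# Ingest a simulated FAERS-dialect database from memory (the generator's
# tables already carry the FAERS column vocabulary).
ingest_sim_faers <- function(sim, meddra = sim_meddra_map(sim$config)) {
  rep <- assemble_reports(sim$faers, "FAERS")
  rep <- remove_deleted_cases(rep, sim$faers$deleted)
  rep <- exclude_country(rep, "JP")
  map_events(rep, meddra)
}

# Full single-database analysis of a simulated dataset: returns the PT-level
# metrics table. Used by recovery and null-rate checks.
analyze_sim <- function(sim, thresholds = default_thresholds()) {
  rep_all <- ingest_sim_faers(sim)
  bg <- event_counts(rep_all, "pt")
  target <- filter_target_drug_ps(rep_all, sim$config$target_drug)
  tg <- event_counts(target, "pt")
  cells <- pvsignal:::drug_event_cells(rep_all, "pt")
  prior <- mgps_fit_prior(cells$a, cells$E, n_random = 0L)
  tabs <- build_tables(tg, bg, "pt")
  compute_disproportionality(tabs, prior, thresholds)
}

# Independent chi-squared oracle: full sum (O - E)^2 / E over the four cells
# from pooled margins.
chi2_expansion <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  o <- cbind(a, b, c, d)
  e <- cbind((a + b) * (a + c), (a + b) * (b + d),
             (c + d) * (a + c), (c + d) * (b + d)) / n
  rowSums((o - e)^2 / e)
}

# Independent numerical oracle for the MGPS posterior: integrate the
# two-component gamma-mixture posterior density directly.
ebgm_numeric <- function(a, E, prior) {
  po <- pvsignal:::mgps_posterior(a, E, prior)
  dens <- function(x) {
    po$q1 * stats::dgamma(x, po$s1, rate = po$r1) +
      (1 - po$q1) * stats::dgamma(x, po$s2, rate = po$r2)
  }
  lo <- min(stats::qgamma(1e-9, po$s1, rate = po$r1),
            stats::qgamma(1e-9, po$s2, rate = po$r2))
  hi <- max(stats::qgamma(1 - 1e-12, po$s1, rate = po$r1),
            stats::qgamma(1 - 1e-12, po$s2, rate = po$r2))
  m <- stats::integrate(function(x) log(x) * dens(x), 0, hi,
                        rel.tol = 1e-10)$value
  q05 <- stats::uniroot(function(x) {
    stats::integrate(dens, 0, x, rel.tol = 1e-10)$value - 0.05
  }, lower = lo, upper = hi, tol = 1e-10)$root
  list(ebgm = exp(m), ebgm05 = q05)
}

random_tables <- function(n, seed) {
  set.seed(seed)
  data.table(a = sample(1:200, n, TRUE),
             b = sample(1:2000, n, TRUE),
             c = sample(1:2000, n, TRUE),
             d = sample(100:50000, n, TRUE))
}
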