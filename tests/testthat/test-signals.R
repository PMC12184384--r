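test_that("a positive signal needs all four algorithms at once", {
  expect_false(intersect_signals(TRUE, TRUE, TRUE, FALSE))
  expect_true(intersect_signals(TRUE, TRUE, TRUE, TRUE))
  expect_false(intersect_signals(FALSE, FALSE, FALSE, FALSE))
  expect_false(intersect_signals(TRUE, NA, TRUE, TRUE))
})

test_that("expectedness is label membership among positives only", {
  m <- data.table(term = c("diarrhoea", "hiccups", "nausea"),
                  positive = c(TRUE, TRUE, FALSE))
  m <- flag_unexpected(m, c("Diarrhoea", "Neutropenia"))
  expect_equal(m$unexpected, c(FALSE, TRUE, FALSE))
  expect_warning(flag_unexpected(m, character(0)), "empty")
})

test_that("cross-database overlap is a plain set intersection", {
  ov <- cross_database_overlap(c("x", "y"), c("Y", "z"))
  expect_equal(ov$overlap, "y")
  expect_equal(ov$a_only, "x")
  expect_equal(ov$b_only, "z")
  expect_equal(cross_database_overlap(c("a"), c("b"))$n_overlap, 0L)
  ident <- cross_database_overlap(c("a", "b"), c("b", "a"))
  expect_equal(ident$overlap, c("a", "b"))
  expect_lte(ov$n_overlap, min(2, 2))
})

test_that("priority scores cut into low / medium / high as specified", {
  # high: very common + >=3 algorithms + >50% fatal is already 6
  s <- score_priority("hepatic failure", 12, 4, 0.6)
  expect_equal(s$total, 6L)
  expect_equal(s$category, "high")
  # medium: common + >=3 algorithms + DME, sub-25% fatality
  s <- score_priority("hepatic failure", 5, 4, 0.1,
                      dme_terms = "hepatic failure")
  expect_equal(s$total, 5L)
  expect_equal(s$category, "medium")
  # low: common + 2 algorithms, nothing else
  s <- score_priority("dehydration", 2, 2, 0.05)
  expect_equal(s$total, 2L)
  expect_equal(s$category, "low")
})

test_that("priority criterion boundaries and DME precedence hold", {
  # reporting rate: 1% scores 1, 10% scores 1, just above 10% scores 2
  expect_equal(score_priority("t", c(0.9, 1, 10, 10.1), 0, 0)$rate_points,
               c(0L, 1L, 1L, 2L))
  # stability: prose rule >=3 -> 2, ==2 -> 1, <=1 -> 0
  expect_equal(score_priority(rep("t", 5), 0, 0:4, 0)$stability_points,
               c(0L, 0L, 1L, 2L, 2L))
  # fatality: 25% scores 1, 50% scores 1, above 50% scores 2
  expect_equal(score_priority(rep("t", 4), 0, 0, c(0.24, 0.25, 0.5, 0.51))$fatality_points,
               c(0L, 1L, 1L, 2L))
  # a term on both lists scores as DME
  s <- score_priority("sepsis", 0, 0, 0, ime_terms = "sepsis",
                      dme_terms = "sepsis")
  expect_equal(s$relevance_points, 2L)
})

test_that("raising any single criterion never lowers the category", {
  grid <- CJ(rate = c(0.5, 5, 15), stab = 0:4, fatal = c(0.1, 0.3, 0.6),
             rel = 0:2)
  lev <- c(low = 1L, medium = 2L, high = 3L)
  cat_of <- function(rate, stab, fatal, rel) {
    lev[score_priority("x", rate, stab, fatal,
                       ime_terms = if (rel >= 1) "x" else character(),
                       dme_terms = if (rel == 2) "x" else character())$category]
  }
  base <- mapply(cat_of, grid$rate, grid$stab, grid$fatal, grid$rel)
  bump_rate <- mapply(cat_of, pmin(grid$rate * 3, 15), grid$stab,
                      grid$fatal, grid$rel)
  bump_stab <- mapply(cat_of, grid$rate, pmin(grid$stab + 1, 4),
                      grid$fatal, grid$rel)
  expect_true(all(bump_rate >= base))
  expect_true(all(bump_stab >= base))
})

test_that("fatality fractions count reports with a death outcome", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  rep <- filter_target_drug_ps(rep, fx$lexicon)
  fat <- term_fatality(rep, c("neutropenia", "hepatic failure", "diarrhoea"))
  # case 202 (neutropenia) and 218 (hepatic failure) carry outcome DE
  expect_equal(fat[term == "hepatic failure", fatality_frac], 1)
  expect_gt(fat[term == "neutropenia", fatality_frac], 0)
  expect_equal(fat[term == "diarrhoea", n_death], 0L)
})

test_that("SOC composition test matches the hand expansion", {
  # A=(50,50), B=(90,10): pooled expectations 70/30 per row;
  # sum (O-E)^2/E = 2*400/70 + 2*400/30 = 38.095 on 1 df
  res <- soc_composition_test(c(s1 = 50, s2 = 50), c(s1 = 90, s2 = 10))
  expect_equal(res$chi2, 2 * 400 / 70 + 2 * 400 / 30, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 1e-8)

  # proportional compositions give a tiny statistic and p near 1
  res2 <- soc_composition_test(c(s1 = 50, s2 = 50), c(s1 = 500, s2 = 500))
  expect_equal(res2$chi2, 0, tolerance = 1e-10)
  expect_gt(res2$p_value, 0.99)

  # a SOC absent from one cohort enters with a zero count, no crash
  res3 <- soc_composition_test(c(s1 = 40, s2 = 10), c(s1 = 30, s3 = 20))
  expect_equal(res3$df, 2)
  expect_error(soc_composition_test(c(s1 = 5), c(s1 = 5)), "two SOC")
})
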