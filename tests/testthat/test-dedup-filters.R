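make_demo <- function(...) {
  rows <- list(...)
  rbindlist(lapply(rows, function(r) {
    data.table(PRIMARYID = r[[1]], CASEID = r[[2]], FDA_DT = r[[3]])
  }))
}

test_that("deduplication keeps the latest receipt date, then the higher id", {
  # same case, different receipt dates: the most recent wins
  d <- make_demo(list("10", "1", "20200101"), list("9", "1", "20210101"))
  expect_equal(deduplicate_faers(d), "9")
  # receipt-date tie: the higher primary id wins
  d <- make_demo(list("10", "1", "20200101"), list("11", "1", "20200101"))
  expect_equal(deduplicate_faers(d), "11")
  # missing receipt date loses to any dated version
  d <- make_demo(list("99", "1", ""), list("5", "1", "20040101"))
  expect_equal(deduplicate_faers(d), "5")
  # non-numeric ids fall back to lexicographic comparison
  d <- make_demo(list("A10", "1", "20200101"), list("A9", "1", "20200101"))
  expect_equal(deduplicate_faers(d), "A9")
})

test_that("deduplication is idempotent and yields one row per case", {
  set.seed(31)
  d <- data.table(PRIMARYID = as.character(sample(1000, 400)),
                  CASEID = as.character(sample(150, 400, TRUE)),
                  FDA_DT = format(as.Date("2015-01-01") +
                                    sample(3000, 400, TRUE), "%Y%m%d"))
  keep1 <- deduplicate_faers(d)
  expect_equal(length(keep1), uniqueN(d$CASEID))
  d2 <- d[PRIMARYID %in% keep1]
  expect_setequal(deduplicate_faers(d2), keep1)
  # all-distinct input is untouched
  d3 <- d[!duplicated(CASEID)]
  expect_setequal(deduplicate_faers(d3), d3$PRIMARYID)
})

test_that("deleted-case removal is an exact set difference", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  n0 <- n_reports(rep)
  r1 <- remove_deleted_cases(rep, c("203", "999999"))  # one hit, one absent
  expect_equal(n_reports(r1), n0 - 1L)
  expect_false("203" %in% r1$demo$case_id)
  expect_equal(unname(attr(r1, "ledger")["dropped_deleted_cases"]), 1L)
  r2 <- remove_deleted_cases(rep, character(0))
  expect_equal(n_reports(r2), n0)
})

test_that("the primary-suspect filter demands lexicon name AND role PS", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  tg <- filter_target_drug_ps(rep, fx$lexicon)
  expect_true("202" %in% tg$demo$case_id)    # IRINOTECAN HYDROCHLORIDE / PS
  expect_false("204" %in% tg$demo$case_id)   # target drug concomitant only
  expect_false("205" %in% tg$demo$case_id)   # no lexicon drug at all
  expect_error(filter_target_drug_ps(rep, character(0)), "empty")
})

test_that("country exclusion drops the code but keeps unknowns", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  rep$demo[case_id == "210", reporter_country := ""]   # blank country
  r1 <- exclude_country(rep, "JP")
  expect_false("206" %in% r1$demo$case_id)
  expect_true("210" %in% r1$demo$case_id)              # unknown is retained
  r2 <- exclude_country(rep, "XX")
  expect_equal(n_reports(r2), n_reports(rep))          # absent code: identity
})

test_that("drug and country filters commute in report counts", {
  cfg <- sim_config(n_reports = 400, seed = 5)
  sim <- simulate_reports(cfg)
  rep <- assemble_reports(sim$faers, "FAERS")
  a <- filter_target_drug_ps(exclude_country(rep, "JP"), cfg$target_drug)
  b <- exclude_country(filter_target_drug_ps(rep, cfg$target_drug), "JP")
  expect_equal(n_reports(a), n_reports(b))
  expect_setequal(a$demo$report_id, b$demo$report_id)
})

test_that("every case is accounted for in the conservation ledger", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  rep <- remove_deleted_cases(rep, fx$faers$deleted)
  rep <- exclude_country(rep, "JP")
  rep <- filter_target_drug_ps(rep, fx$lexicon)
  led <- attr(rep, "ledger")
  expect_equal(unname(led["retained_after_dedup"]),
               n_reports(rep) + unname(led["dropped_deleted_cases"]) +
                 unname(led["dropped_country_JP"]) +
                 unname(led["dropped_not_target_ps"]))
  expect_setequal(rep$demo$case_id, fx$expected$retained_cases)
})

test_that("SOC mapping is case-insensitive and carries unmapped terms", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  rep$events[1, pt := "DIARRHOEA"]   # case variant must still map
  map <- copy(fx$meddra_map)
  rep <- map_events(rep, map)
  expect_equal(rep$events$soc[1], "Gastrointestinal disorders")
  rep2 <- assemble_reports(fx$faers, "FAERS")
  rep2$events[1, pt := "not a real term"]
  rep2 <- map_events(rep2, map)
  expect_equal(rep2$events$soc[1], "UNMAPPED")
  expect_equal(unname(attr(rep2, "ledger")["unmapped_pt_rows"]), 1L)
})

test_that("monotherapy restriction drops any report with other drugs", {
  fx <- fixture_small()
  rep <- assemble_reports(fx$faers, "FAERS")
  rep <- filter_target_drug_ps(rep, fx$lexicon)
  mono <- sensitivity_monotherapy(rep, fx$lexicon)
  expect_false("215" %in% mono$demo$case_id)  # carries concomitant FLUOROURACIL
  expect_false("218" %in% mono$demo$case_id)  # secondary-suspect BEVACIZUMAB
  expect_true("216" %in% mono$demo$case_id)   # target drug only
  expect_lte(n_reports(mono), n_reports(rep))
})
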