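make_reports <- function(sex, age = NULL, country = NULL, outc = NULL) {
  n <- length(sex)
  demo <- data.table(
    report_id = as.character(seq_len(n)), case_id = as.character(seq_len(n)),
    source_db = "FAERS", receipt_token = "20200101", receipt_year = 2020L,
    sex = sex,
    age_years = if (is.null(age)) rep(NA_real_, n) else age,
    weight_kg = NA_real_,
    reporter_country = if (is.null(country)) rep("US", n) else country,
    occr_country = "US", event_token = NA_character_,
    event_precision = "none")
  empty <- function(...) data.table(...)
  out <- if (is.null(outc)) empty(report_id = character(), code = character())
         else data.table(report_id = as.character(seq_along(outc)), code = outc)
  pvsignal:::new_safety_reports(
    demo,
    empty(report_id = character(), name_verbatim = character(),
          name_norm = character(), role_code = character(),
          start_token = character(), start_precision = character()),
    empty(report_id = character(), pt = character(), pt_verbatim = character(),
          soc = character(), event_token = character(),
          event_precision = character(), outcome = character()),
    out,
    empty(report_id = character(), term = character()),
    empty(report_id = character(), start_token = character(),
          start_precision = character()),
    "FAERS")
}

test_that("demographic shares use the report count as denominator", {
  rep <- make_reports(sex = c(rep("M", 6), rep("F", 3), "U"))
  s <- summarize_demographics(rep)
  expect_equal(s[section == "sex" & category == "Male", pct], 60.0)
  expect_equal(s[section == "sex" & category == "Female", pct], 30.0)
  expect_equal(s[section == "sex", sum(n)], 10L)
})

test_that("fully missing fields fall into explicit unknown rows", {
  rep <- make_reports(sex = rep("U", 4))
  s <- summarize_demographics(rep)
  expect_equal(s[section == "sex" & category == "Unknown", pct], 100)
  expect_equal(s[section == "age" & category == "Unknown", pct], 100)
  expect_equal(s[section == "weight" & category == "Unknown", pct], 100)
})

test_that("age bands follow the database convention", {
  rep <- make_reports(sex = rep("M", 5), age = c(10, 30, 65, 66, NA))
  s <- summarize_demographics(rep)
  expect_equal(s[section == "age" & category == "18-65 years", n], 2L)
  expect_equal(s[section == "age" & category == ">65 years", n], 1L)
  expect_equal(s[section == "age" & category == "<18 years", n], 1L)
  expect_equal(s[section == "age" & category == "Unknown", n], 1L)
})

test_that("FAERS outcome shares divide by reports, JADER by outcome entries", {
  rep <- make_reports(sex = rep("M", 10), outc = c(rep("DE", 2), rep("HO", 3)))
  s <- summarize_demographics(rep)
  expect_equal(s[section == "outcome" & category == "DE", pct], 20.0)

  # JADER-style: outcomes are per reaction entry, more entries than reports
  repj <- make_reports(sex = rep("M", 10))
  attr(repj, "source_db") <- "JADER"
  repj$outcomes <- data.table(report_id = as.character(rep(1:10, each = 2)),
                              code = c(rep("死亡", 3), rep("回復", 17)))
  sj <- summarize_demographics(repj)
  expect_equal(sj[section == "outcome" & category == "死亡", pct], 15.0)
  expect_equal(sj[section == "outcome" & category == "死亡", denominator], 20L)
})
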