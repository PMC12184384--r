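test_that("identical seeds give byte-identical output files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- sim_config(n_reports = 150, seed = 23,
                    signals = data.frame(pt = "pt_005", lambda = 4))
  simulate_reports(cfg, out_dir = d1)
  simulate_reports(cfg, out_dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 8)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("a zero duplicate rate yields unique case ids", {
  cfg <- sim_config(n_reports = 200, seed = 4, duplicate_rate = 0)
  sim <- simulate_reports(cfg)
  expect_equal(anyDuplicated(sim$faers$demo$CASEID), 0L)
  cfg2 <- sim_config(n_reports = 200, seed = 4, duplicate_rate = 0.3)
  sim2 <- simulate_reports(cfg2)
  expect_gt(anyDuplicated(sim2$faers$demo$CASEID), 0L)
})

test_that("infeasible configurations fail before any file is written", {
  expect_error(sim_config(n_reports = 10, seed = 1,
                          signals = data.frame(pt = "pt_001", lambda = -2)),
               "lambda")
  expect_error(sim_config(n_reports = 10, seed = 1,
                          signals = data.frame(pt = "nope", lambda = 2)),
               "vocabulary")
  expect_error(sim_config(n_reports = 10, seed = 1, duplicate_rate = 1.4),
               "probabilities")
  expect_error(sim_config(n_reports = 10), "seed")
})

test_that("planted counts match ground-truth expectations within 3 SD", {
  cfg <- sim_config(n_reports = 8000, seed = 61,
                    signals = data.frame(pt = c("pt_012", "pt_040"),
                                         lambda = c(8, 3)))
  sim <- simulate_reports(cfg)
  rep <- ingest_sim_faers(sim)
  tg <- filter_target_drug_ps(rep, cfg$target_drug)
  counts <- event_counts(tg, "pt")
  tr <- sim$truth$signals
  for (p in c("pt_012", "pt_040", "pt_001", "pt_030")) {
    exp_a <- tr[pt == p, expected_a]
    n_t <- tr[pt == p, n_clean_target]
    sd3 <- 3 * sqrt(exp_a * (1 - exp_a / n_t))
    got <- counts[term == p, n]
    if (length(got) == 0) got <- 0L
    expect_lt(abs(got - exp_a), sd3 + 1e-9, label = p)
  }
})

test_that("generate -> ingest -> contingency recovers planted counts exactly", {
  # duplicate-free, deletion-free, single-country world: the pipeline must
  # return precisely the counts present in the raw event file
  cfg <- sim_config(n_reports = 500, seed = 9, duplicate_rate = 0,
                    deleted_rate = 0, country_mix = c(US = 1),
                    signals = data.frame(pt = "pt_003", lambda = 6))
  sim <- simulate_reports(cfg)
  rep <- ingest_sim_faers(sim)
  tg <- filter_target_drug_ps(rep, cfg$target_drug)
  tabs <- build_tables(event_counts(tg, "pt"), event_counts(rep, "pt"), "pt")

  truth_target <- sim$truth$reports[is_target == TRUE, primaryid]
  raw_pairs <- unique(sim$faers$reac[PRIMARYID %in% truth_target,
                                     .(PRIMARYID, PT)])
  raw_counts <- raw_pairs[, .N, by = PT]
  expect_equal(stats::setNames(tabs$a, tabs$term)[raw_counts$PT],
               stats::setNames(as.numeric(raw_counts$N), raw_counts$PT))
  expect_equal(sum(tabs$a), nrow(raw_pairs))
})

test_that("dedup semantics are observable on generated duplicates", {
  cfg <- sim_config(n_reports = 400, seed = 17, duplicate_rate = 0.2)
  sim <- simulate_reports(cfg)
  keep <- deduplicate_faers(sim$faers$demo)
  dup_links <- sim$truth$reports[duplicated == TRUE]
  # the later-dated resubmission must always win
  expect_true(all(dup_links$duplicate_primaryid %in% keep))
  expect_false(any(dup_links$primaryid %in% keep))
  expect_equal(length(keep), uniqueN(sim$faers$demo$CASEID))
})

test_that("both dialects carry the same underlying truth", {
  cfg <- sim_config(n_reports = 300, seed = 29, duplicate_rate = 0)
  dir <- withr::local_tempdir()
  sim <- simulate_reports(cfg, out_dir = dir)
  jp <- parse_jader_tables(file.path(dir, "jader"), encoding = "UTF-8")
  jrep <- assemble_reports(jp, "JADER")
  frep <- assemble_reports(sim$faers, "FAERS")
  expect_equal(n_reports(jrep), n_reports(frep))
  # per-term event counts agree across dialects
  jc <- event_counts(map_events(jrep, sim_meddra_map(cfg)), "pt")
  fc <- event_counts(map_events(frep, sim_meddra_map(cfg)), "pt")
  expect_equal(jc[order(term)], fc[order(term)])
})
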