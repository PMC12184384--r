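# End-to-end orchestration: ingest -> contingency -> disproportionality ->
# classification -> time to onset, per database, plus cross-database
# comparisons and a machine-readable run manifest.

# Drug-event cells over the whole database (one count per distinct
# report/drug/term triple, PS drugs only) with their independence
# expectations; this is what the MGPS prior is fitted on.
drug_event_cells <- function(reports, level = "pt") {
  ps <- unique(reports$drugs[role_code == "PS", .(report_id, drug = name_norm)])
  ev <- unique(reports$events[, .(report_id, term = get(level))])
  ev <- ev[!is.na(term) & nzchar(term)]
  cells <- unique(merge(ps, ev, by = "report_id",
                        allow.cartesian = TRUE))[, .(a = .N), by = .(drug, term)]
  drug_tot <- cells[, .(nd = sum(a)), by = drug]
  term_tot <- cells[, .(nt = sum(a)), by = term]
  total <- sum(cells$a)
  cells <- merge(cells, drug_tot, by = "drug")
  cells <- merge(cells, term_tot, by = "term")
  cells[, E := nd * nt / total]
  cells[]
}

#' Fit the MGPS prior on a whole-database report collection
#'
#' Builds every drug-event cell (primary-suspect drugs, distinct terms per
#' report) and fits the gamma-mixture prior on the full cell set, as the
#' empirical-Bayes method prescribes — not only on the target drug's cells.
#'
#' @param reports a `safety_reports` object covering all drugs.
#' @param level `"pt"` or `"soc"`.
#' @param seed passed to [mgps_fit_prior()].
#' @return an `mgps_prior`.
#' @export
mgps_prior_from_reports <- function(reports, level = "pt", seed = 1L) {
  cells <- drug_event_cells(reports, level)
  mgps_fit_prior(cells$a, cells$E, seed = seed)
}

analyze_database <- function(reports_all, lexicon, label_terms, ime_terms,
                             dme_terms, thresholds, seed,
                             tto_min_n = 10L) {
  # background = full database after case-level cleaning
  bg_pt <- event_counts(reports_all, "pt")
  bg_soc <- event_counts(reports_all, "soc")
  target <- filter_target_drug_ps(reports_all, lexicon)
  if (n_reports(target) == 0L) stop("no reports left after the target-drug filter")
  tg_pt <- event_counts(target, "pt")
  tg_soc <- event_counts(target, "soc")

  prior <- mgps_prior_from_reports(reports_all, "pt", seed = seed)
  tab_pt <- build_tables(tg_pt, bg_pt, "pt")
  tab_soc <- build_tables(tg_soc, bg_soc, "soc")
  met_pt <- compute_disproportionality(tab_pt, prior, thresholds)
  met_soc <- compute_disproportionality(tab_soc, prior, thresholds)
  met_pt <- flag_unexpected(met_pt, label_terms)

  total_events <- sum(tg_pt$n)
  met_pt[, rate_pct := reporting_rate(a, total_events)]
  fat <- term_fatality(target, met_pt$term)
  met_pt <- merge(met_pt, fat[, .(term, fatality_frac)], by = "term",
                  sort = FALSE)
  pr <- score_priority(met_pt$term, met_pt$rate_pct, met_pt$n_flags,
                       met_pt$fatality_frac, ime_terms, dme_terms)
  met_pt[, `:=`(priority_total = pr$total, priority_category = pr$category)]
  data.table::setorder(met_pt, -a)

  tto <- compute_tto(target)
  tto_sum <- NULL
  wfit <- NULL
  inc <- tto[status == "included", tto_days]
  if (length(inc) >= 1L) tto_sum <- summarize_tto(inc)
  if (length(inc) >= tto_min_n && stats::sd(inc) > 0) {
    wfit <- weibull_fit(inc)
  }

  list(reports_all = reports_all, target = target,
       demographics = summarize_demographics(target),
       annual = annual_counts(target),
       prior = prior,
       tables_pt = tab_pt, tables_soc = tab_soc,
       metrics_pt = met_pt, metrics_soc = met_soc,
       tto = tto, tto_summary = tto_sum, weibull = wfit,
       positive_terms = met_pt[positive == TRUE, term])
}

#' Run the full signal-detection pipeline
#'
#' Executes ingest, deduplication, filtering, contingency, the four
#' disproportionality algorithms, signal classification with priority
#' scoring, and time-to-onset analysis for a FAERS-dialect and/or a
#' JADER-dialect source, then (when both are present) the cross-database
#' overlap and the SOC composition chi-squared comparison. With `out_dir`
#' set it writes the demographics, SOC signal, PT signal, overlap,
#' priority, sensitivity and TTO summary tables as TSV plus a run manifest
#' (seed, thresholds, per-stage report counts) as JSON.
#'
#' @param faers_dir,jader_dir source directories (either may be `NULL`).
#' @param lexicon drug-name lexicon: character vector or path for the
#'   FAERS-dialect names.
#' @param jader_lexicon lexicon for the JADER-dialect names (defaults to
#'   the target drug's Japanese spelling plus `lexicon`).
#' @param meddra_map PT->SOC map: `data.table` or TSV path.
#' @param label_terms,ime_terms,dme_terms character vectors or paths.
#' @param exclude_country country code removed from the FAERS stream
#'   (`NULL` to skip).
#' @param thresholds list from [default_thresholds()].
#' @param jader_encoding encoding of the JADER files.
#' @param out_dir optional output directory.
#' @param seed RNG seed (MGPS prior multistart).
#' @return list with one element per database (`faers`, `jader`), plus
#'   `overlap`, `soc_test` and `manifest`.
#' @export
run_pipeline <- function(faers_dir = NULL, jader_dir = NULL, lexicon,
                         jader_lexicon = NULL, meddra_map,
                         label_terms = character(),
                         ime_terms = character(), dme_terms = character(),
                         exclude_country = "JP",
                         thresholds = default_thresholds(),
                         jader_encoding = "UTF-8",
                         out_dir = NULL, seed = 1L) {
  as_terms <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) load_term_list(x)
    else normalize_term(x)
  }
  lexicon <- if (is.character(lexicon) && length(lexicon) == 1L &&
                 file.exists(lexicon)) load_term_list(lexicon) else lexicon
  if (is.character(meddra_map) && length(meddra_map) == 1L) {
    meddra_map <- load_meddra_map(meddra_map)
  }
  label_terms <- as_terms(label_terms)
  ime_terms <- as_terms(ime_terms)
  dme_terms <- as_terms(dme_terms)

  res <- list()
  if (!is.null(faers_dir)) {
    parsed <- parse_faers_quarter(faers_dir)
    rep_all <- assemble_reports(parsed, "FAERS")
    rep_all <- remove_deleted_cases(rep_all, parsed$deleted)
    if (!is.null(exclude_country)) {
      rep_all <- exclude_country(rep_all, exclude_country)
    }
    rep_all <- map_events(rep_all, meddra_map)
    res$faers <- analyze_database(rep_all, lexicon, label_terms, ime_terms,
                                  dme_terms, thresholds, seed)
  }
  if (!is.null(jader_dir)) {
    parsed <- parse_jader_tables(jader_dir, encoding = jader_encoding)
    rep_all <- assemble_reports(parsed, "JADER")
    rep_all <- map_events(rep_all, meddra_map)
    jlex <- jader_lexicon %||% unique(c("イリノテカン", lexicon))
    res$jader <- analyze_database(rep_all, jlex, label_terms, ime_terms,
                                  dme_terms, thresholds, seed)
  }

  if (!is.null(res$faers) && !is.null(res$jader)) {
    res$overlap <- cross_database_overlap(res$faers$positive_terms,
                                          res$jader$positive_terms)
    ca <- stats::setNames(res$faers$tables_soc$a, res$faers$tables_soc$term)
    cb <- stats::setNames(res$jader$tables_soc$a, res$jader$tables_soc$term)
    res$soc_test <- soc_composition_test(ca, cb)
  }

  res$manifest <- list(
    pvsignal_version = as.character(utils::packageVersion("pvsignal")),
    seed = seed,
    thresholds = thresholds,
    counts = lapply(res[intersect(names(res), c("faers", "jader"))],
                    function(db) {
                      c(as.list(attr(db$target, "ledger")),
                        list(target_reports = n_reports(db$target),
                             target_events = sum(event_counts(db$target, "pt")$n),
                             positive_signals = length(db$positive_terms)))
                    }))

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x)) data.table::fwrite(x, file.path(out_dir, name), sep = "\t")
  }
  for (db in intersect(names(res), c("faers", "jader"))) {
    r <- res[[db]]
    w(r$demographics, paste0(db, "_demographics.tsv"))
    w(r$annual, paste0(db, "_annual_counts.tsv"))
    write_signal_table(r$metrics_soc, file.path(out_dir, paste0(db, "_soc_signals.tsv")))
    write_signal_table(r$metrics_pt, file.path(out_dir, paste0(db, "_pt_signals.tsv")))
    w(r$metrics_pt[positive == TRUE,
                   .(term, a, rate_pct, priority_total, priority_category)],
      paste0(db, "_priority.tsv"))
    w(r$tto, paste0(db, "_tto_records.tsv"))
    if (!is.null(r$tto_summary)) {
      w(r$tto_summary$bins, paste0(db, "_tto_bins.tsv"))
      w(data.table::data.table(
        n = r$tto_summary$n, median = r$tto_summary$median,
        q1 = r$tto_summary$q1, q3 = r$tto_summary$q3,
        weibull_scale = if (is.null(r$weibull)) NA_real_ else r$weibull$scale,
        weibull_shape = if (is.null(r$weibull)) NA_real_ else r$weibull$shape,
        shape_ci_low = if (is.null(r$weibull)) NA_real_ else r$weibull$shape_low,
        shape_ci_high = if (is.null(r$weibull)) NA_real_ else r$weibull$shape_high,
        hazard_class = if (is.null(r$weibull)) NA_character_
                       else classify_hazard(r$weibull)),
        paste0(db, "_tto_summary.tsv"))
    }
  }
  if (!is.null(res$overlap)) {
    w(data.table::data.table(
      term = c(res$overlap$overlap, res$overlap$a_only, res$overlap$b_only),
      set = rep(c("overlap", "a_only", "b_only"),
                c(res$overlap$n_overlap, res$overlap$n_a_only,
                  res$overlap$n_b_only))),
      "overlap.tsv")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
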