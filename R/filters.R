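#' Remove cases named on a deleted-report list
#'
#' Quarterly FAERS packages ship a list of case ids withdrawn by the FDA;
#' every retained report whose case id appears on the list is dropped.
#'
#' @param reports a `safety_reports` object.
#' @param deleted_ids character vector of case ids.
#' @return filtered `safety_reports`; the number removed is recorded in the
#'   ledger under `"dropped_deleted_cases"`.
#' @export
remove_deleted_cases <- function(reports, deleted_ids) {
  deleted_ids <- as.character(deleted_ids)
  keep <- reports$demo[!case_id %in% deleted_ids, report_id]
  restrict_reports(reports, keep, "dropped_deleted_cases")
}

#' Keep reports where a lexicon drug is the primary suspect
#'
#' Retains reports having at least one drug entry whose normalized verbatim
#' name matches the lexicon exactly and whose role code is `PS`. Reports
#' mentioning a lexicon drug only as secondary suspect, concomitant or
#' interacting are dropped, as are reports with no lexicon drug at all.
#'
#' @param reports a `safety_reports` object.
#' @param lexicon character vector of drug names (normalized internally).
#' @return filtered `safety_reports` (ledger rule
#'   `"dropped_not_target_ps"`).
#' @export
filter_target_drug_ps <- function(reports, lexicon) {
  lexicon <- normalize_term(lexicon)
  lexicon <- lexicon[nzchar(lexicon)]
  if (length(lexicon) == 0L) stop("drug lexicon is empty")
  keep <- unique(reports$drugs[name_norm %in% lexicon & role_code == "PS",
                               report_id])
  restrict_reports(reports, keep, "dropped_not_target_ps")
}

#' Exclude reports from one country
#'
#' Used to drop Japan-origin reports from the FAERS stream so cases are not
#' double-counted against JADER. Reports with a blank or unknown country are
#' retained (unknown is not the excluded country).
#'
#' @param reports a `safety_reports` object.
#' @param country country code, e.g. `"JP"`.
#' @param field `"reporter"` (default) or `"occurrence"` country field.
#' @return filtered `safety_reports` (ledger rule `"dropped_country_<code>"`).
#' @export
exclude_country <- function(reports, country = "JP",
                            field = c("reporter", "occurrence")) {
  field <- match.arg(field)
  col <- if (field == "reporter") "reporter_country" else "occr_country"
  val <- toupper(trimws(reports$demo[[col]]))
  keep <- reports$demo$report_id[is.na(val) | val != toupper(country)]
  restrict_reports(reports, keep, paste0("dropped_country_", toupper(country)))
}

#' Annotate events with their system organ class
#'
#' Looks every preferred term up in the PT->SOC map (after normalization);
#' terms absent from the map are carried with `soc = "UNMAPPED"` rather than
#' dropped, and the unmapped count is recorded in the ledger.
#'
#' @param reports a `safety_reports` object.
#' @param meddra_map a table from [load_meddra_map()] (columns `pt`, `soc`).
#' @return `safety_reports` with the `soc` column of `$events` filled.
#' @export
map_events <- function(reports, meddra_map) {
  idx <- match(normalize_term(reports$events$pt), normalize_term(meddra_map$pt))
  reports$events[, soc := ifelse(is.na(idx), "UNMAPPED", meddra_map$soc[idx])]
  ledger_add(reports, "unmapped_pt_rows", sum(is.na(idx)))
}

#' Restrict to monotherapy reports
#'
#' Sensitivity analysis subset: keeps reports whose entire drug list matches
#' the target lexicon (no concomitant, secondary-suspect or interacting drug
#' of any other name), so that disproportionality can be recomputed free of
#' co-medication confounding.
#'
#' @inheritParams filter_target_drug_ps
#' @return filtered `safety_reports` (ledger rule `"dropped_comedication"`).
#' @export
sensitivity_monotherapy <- function(reports, lexicon) {
  lexicon <- normalize_term(lexicon)
  if (length(lexicon) == 0L) stop("drug lexicon is empty")
  other <- unique(reports$drugs[!name_norm %in% lexicon, report_id])
  keep <- setdiff(reports$demo$report_id, other)
  if (length(keep) == 0L) {
    stop("monotherapy subset is empty: every report carries a non-lexicon drug")
  }
  restrict_reports(reports, keep, "dropped_comedication")
}
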