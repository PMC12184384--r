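# The safety_reports container: one deduplicated case per row of $demo,
# with child tables keyed by report_id. A conservation ledger (named counts
# of reports dropped by each rule) is carried in the "ledger" attribute so
# the filtering flow can be reconstructed from the object alone.

new_safety_reports <- function(demo, drugs, events, outcomes, indications,
                               therapy, source_db, ledger = integer()) {
  obj <- list(demo = demo, drugs = drugs, events = events,
              outcomes = outcomes, indications = indications,
              therapy = therapy)
  attr(obj, "source_db") <- source_db
  attr(obj, "ledger") <- ledger
  class(obj) <- "safety_reports"
  obj
}

#' @export
print.safety_reports <- function(x, ...) {
  cat(sprintf("<safety_reports> %s: %d reports, %d drug rows, %d event rows\n",
              attr(x, "source_db"), nrow(x$demo), nrow(x$drugs), nrow(x$events)))
  led <- attr(x, "ledger")
  if (length(led)) {
    cat("ledger:\n")
    for (nm in names(led)) cat(sprintf("  %-28s %d\n", nm, led[[nm]]))
  }
  invisible(x)
}

#' Number of retained reports
#' @param x a `safety_reports` object.
#' @export
n_reports <- function(x) nrow(x$demo)

ledger_add <- function(x, name, count) {
  led <- attr(x, "ledger")
  led[name] <- as.integer(count)
  attr(x, "ledger") <- led
  x
}

# Restrict every child table to a set of report ids, recording the drop.
restrict_reports <- function(x, keep_ids, rule) {
  dropped <- nrow(x$demo) - length(keep_ids)
  for (tab in c("demo", "drugs", "events", "outcomes", "indications", "therapy")) {
    if (!is.null(x[[tab]]) && nrow(x[[tab]])) {
      x[[tab]] <- x[[tab]][report_id %in% keep_ids]
    }
  }
  ledger_add(x, rule, dropped)
}

#' Deduplicate FAERS case versions
#'
#' FAERS republishes cases across quarters; among rows sharing a CASEID the
#' FDA deduplication rule keeps the most recent FDA_DT, breaking receipt-date
#' ties by the higher PRIMARYID (numeric comparison when both ids parse as
#' integers, else lexicographic). A missing FDA_DT sorts lowest, so any dated
#' version of a case wins over an undated one.
#'
#' @param demo a `data.table` with columns `PRIMARYID`, `CASEID`, `FDA_DT`
#'   (as read by [parse_faers_quarter()]).
#' @return character vector of retained PRIMARYIDs, one per distinct CASEID.
#' @export
deduplicate_faers <- function(demo) {
  stopifnot(all(c("PRIMARYID", "CASEID") %in% names(demo)))
  d <- data.table::data.table(
    pid = as.character(demo$PRIMARYID),
    cid = as.character(demo$CASEID),
    key_dt = if ("FDA_DT" %in% names(demo)) receipt_sort_key(demo$FDA_DT)
             else rep(-Inf, nrow(demo))
  )
  pid_num <- suppressWarnings(as.numeric(d$pid))
  # numeric tie-break key where ids parse, else rank of the lexicographic order
  d[, key_pid := if (all(!is.na(pid_num))) pid_num else as.numeric(order(order(pid)))]
  d[, row := .I]
  keep <- d[order(cid, -key_dt, -key_pid), .SD[1], by = cid]
  d$pid[keep$row]
}

# Map FAERS age value+unit to years.
faers_age_years <- function(age, cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(cod))
  mult <- rep(1, length(v))
  mult[cod == "MON"] <- 1 / 12
  mult[cod == "WK"] <- 1 / 52.18
  mult[cod == "DY"] <- 1 / 365.25
  mult[cod == "HR"] <- 1 / 8766
  mult[cod == "DEC"] <- 10
  v * mult
}

#' Assemble parsed raw tables into a report collection
#'
#' Joins the per-file row collections of one database into a
#' `safety_reports` object keyed by report id. For FAERS the report id is
#' the retained PRIMARYID (pass the result of [deduplicate_faers()]); for
#' JADER the latest report sequence per case number is retained.
#'
#' @param parsed output of [parse_faers_quarter()] or [parse_jader_tables()].
#' @param source_db `"FAERS"` or `"JADER"`.
#' @param retained_ids for FAERS, the PRIMARYIDs to keep (defaults to
#'   deduplicating internally).
#' @return a `safety_reports` object; events are not yet SOC-coded
#'   (see [map_events()]).
#' @export
assemble_reports <- function(parsed, source_db = c("FAERS", "JADER"),
                             retained_ids = NULL) {
  source_db <- match.arg(source_db)
  if (source_db == "FAERS") assemble_faers(parsed, retained_ids)
  else assemble_jader(parsed)
}

assemble_faers <- function(parsed, retained_ids = NULL) {
  demo <- parsed$demo
  n_raw <- nrow(demo)
  if (is.null(retained_ids)) retained_ids <- deduplicate_faers(demo)
  demo <- demo[match(retained_ids, as.character(demo$PRIMARYID))]
  getcol <- function(dt, nm) if (nm %in% names(dt)) as.character(dt[[nm]]) else rep("", nrow(dt))

  sex <- toupper(trimws(getcol(demo, "SEX")))
  sex[!sex %in% c("F", "M")] <- "U"
  ev <- parse_date_token(getcol(demo, "EVENT_DT"))
  d <- data.table::data.table(
    report_id = as.character(demo$PRIMARYID),
    case_id = as.character(demo$CASEID),
    source_db = "FAERS",
    receipt_token = getcol(demo, "FDA_DT"),
    receipt_year = parse_date_token(getcol(demo, "FDA_DT"))$year,
    sex = sex,
    age_years = faers_age_years(getcol(demo, "AGE"), getcol(demo, "AGE_COD")),
    weight_kg = suppressWarnings(as.numeric(getcol(demo, "WT"))),
    reporter_country = toupper(trimws(getcol(demo, "REPORTER_COUNTRY"))),
    occr_country = toupper(trimws(getcol(demo, "OCCR_COUNTRY"))),
    event_token = getcol(demo, "EVENT_DT"),
    event_precision = ev$precision
  )

  keep <- function(dt) dt[as.character(dt$PRIMARYID) %in% d$report_id]
  drug <- keep(parsed$drug)
  st <- parse_date_token(getcol(drug, "START_DT"))
  drugs <- data.table::data.table(
    report_id = as.character(drug$PRIMARYID),
    name_verbatim = getcol(drug, "DRUGNAME"),
    name_norm = normalize_term(getcol(drug, "DRUGNAME")),
    role_code = toupper(trimws(getcol(drug, "ROLE_COD"))),
    start_token = getcol(drug, "START_DT"),
    start_precision = st$precision
  )
  reac <- keep(parsed$reac)
  events <- data.table::data.table(
    report_id = as.character(reac$PRIMARYID),
    pt = normalize_term(getcol(reac, "PT")),
    pt_verbatim = getcol(reac, "PT"),
    soc = NA_character_,
    event_token = NA_character_,
    event_precision = "none",
    outcome = NA_character_
  )
  events <- events[nzchar(pt)]
  outcomes <- if (!is.null(parsed$outc)) {
    o <- keep(parsed$outc)
    data.table::data.table(report_id = as.character(o$PRIMARYID),
                           code = toupper(trimws(getcol(o, "OUTC_COD"))))
  } else data.table::data.table(report_id = character(), code = character())
  indications <- if (!is.null(parsed$indi)) {
    i <- keep(parsed$indi)
    unique(data.table::data.table(report_id = as.character(i$PRIMARYID),
                                  term = normalize_term(getcol(i, "INDI_PT"))))
  } else data.table::data.table(report_id = character(), term = character())
  therapy <- if (!is.null(parsed$ther)) {
    t <- keep(parsed$ther)
    stt <- parse_date_token(getcol(t, "START_DT"))
    data.table::data.table(report_id = as.character(t$PRIMARYID),
                           start_token = getcol(t, "START_DT"),
                           start_precision = stt$precision)
  } else data.table::data.table(report_id = character(),
                                start_token = character(),
                                start_precision = character())

  x <- new_safety_reports(d, drugs, events, outcomes, indications, therapy, "FAERS")
  x <- ledger_add(x, "raw_case_rows", n_raw)
  x <- ledger_add(x, "dropped_duplicate_versions", n_raw - nrow(d))
  ledger_add(x, "retained_after_dedup", nrow(d))
}

assemble_jader <- function(parsed) {
  demo <- parsed$demo
  n_raw <- nrow(demo)
  # one row per case: the latest report sequence is the current version
  demo[, seq_n := suppressWarnings(as.numeric(seq))]
  demo[is.na(seq_n), seq_n := 1]
  demo <- demo[order(case_id, -seq_n), .SD[1], by = case_id]

  sex <- trimws(demo$sex)
  sex_std <- rep("U", length(sex))
  sex_std[sex %in% c("男性", "M", "male")] <- "M"
  sex_std[sex %in% c("女性", "F", "female")] <- "F"

  d <- data.table::data.table(
    report_id = demo$case_id,
    case_id = demo$case_id,
    source_db = "JADER",
    receipt_token = demo$receipt,
    receipt_year = parse_date_token(demo$receipt)$year,
    sex = sex_std,
    age_years = jader_age_years(demo$age),
    weight_kg = jader_weight_kg(demo$weight),
    reporter_country = "JP",
    occr_country = "JP",
    event_token = NA_character_,
    event_precision = "none"
  )
  drug <- parsed$drug[case_id %in% d$report_id]
  st <- parse_date_token(drug$start)
  drugs <- data.table::data.table(
    report_id = drug$case_id,
    name_verbatim = drug$name,
    name_norm = normalize_term(drug$name),
    role_code = drug$role_code,
    start_token = drug$start,
    start_precision = st$precision
  )
  reac <- parsed$reac[case_id %in% d$report_id]
  ev <- parse_date_token(reac$event_date)
  events <- data.table::data.table(
    report_id = reac$case_id,
    pt = normalize_term(reac$pt),
    pt_verbatim = reac$pt,
    soc = NA_character_,
    event_token = reac$event_date,
    event_precision = ev$precision,
    outcome = trimws(reac$outcome)
  )
  events <- events[nzchar(pt)]
  outcomes <- data.table::data.table(report_id = events$report_id,
                                     code = events$outcome)
  indications <- if (!is.null(parsed$hist)) {
    h <- parsed$hist[case_id %in% d$report_id]
    unique(data.table::data.table(report_id = h$case_id,
                                  term = normalize_term(h$indication)))
  } else data.table::data.table(report_id = character(), term = character())
  therapy <- drugs[role_code == "PS", .(report_id, start_token, start_precision)]

  x <- new_safety_reports(d, drugs, events, outcomes, indications, therapy, "JADER")
  x <- ledger_add(x, "raw_case_rows", n_raw)
  x <- ledger_add(x, "dropped_duplicate_versions", n_raw - nrow(d))
  ledger_add(x, "retained_after_dedup", nrow(d))
}
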