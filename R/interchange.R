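# Internal interchange format: one report per line as a JSON record holding
# the demographic row plus the report's drug, event, outcome, indication and
# therapy rows. Round-trips a safety_reports object field-for-field.

#' Write a report collection to the one-report-per-line interchange format
#'
#' @param reports a `safety_reports` object.
#' @param path output file (ndjson).
#' @return `path`, invisibly.
#' @seealso [read_reports()]
#' @export
write_reports <- function(reports, path) {
  ids <- reports$demo$report_id
  drugs <- split(reports$drugs, by = "report_id")
  events <- split(reports$events, by = "report_id")
  outcomes <- split(reports$outcomes, by = "report_id")
  indications <- split(reports$indications, by = "report_id")
  therapy <- split(reports$therapy, by = "report_id")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    id <- ids[i]
    rec <- list(
      demo = as.list(reports$demo[i]),
      drugs = drugs[[id]],
      events = events[[id]],
      outcomes = outcomes[[id]],
      indications = indications[[id]],
      therapy = therapy[[id]]
    )
    writeLines(jsonlite::toJSON(rec, dataframe = "rows", na = "null",
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a report collection from the interchange format
#'
#' @param path file written by [write_reports()].
#' @param source_db database label to stamp on the object.
#' @return a `safety_reports` object.
#' @export
read_reports <- function(path, source_db = c("FAERS", "JADER")) {
  source_db <- match.arg(source_db)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  bind <- function(nm, template) {
    parts <- lapply(recs, function(r) {
      p <- r[[nm]]
      if (is.null(p) || length(p) == 0L) return(NULL)
      dt <- data.table::as.data.table(p)
      if (!"report_id" %in% names(dt)) dt[, report_id := r$demo$report_id]
      dt
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0L) return(template)
    out <- data.table::rbindlist(parts, fill = TRUE)
    out[, report_id := as.character(report_id)]
    # all-null JSON columns come back logical; restore the template types
    for (nm2 in names(template)) {
      if (!nm2 %in% names(out)) {
        out[, (nm2) := methods::as(NA, class(template[[nm2]]))]
      } else if (!identical(class(out[[nm2]]), class(template[[nm2]]))) {
        out[, (nm2) := methods::as(out[[nm2]], class(template[[nm2]]))]
      }
    }
    out
  }
  demo <- data.table::rbindlist(lapply(recs, function(r) {
    data.table::as.data.table(lapply(r$demo, function(v) if (is.null(v)) NA else v))
  }), fill = TRUE)
  demo[, report_id := as.character(report_id)]
  demo[, case_id := as.character(case_id)]
  if ("event_token" %in% names(demo)) demo[, event_token := as.character(event_token)]
  empty <- function(...) data.table::data.table(...)
  x <- new_safety_reports(
    demo,
    bind("drugs", empty(report_id = character(), name_verbatim = character(),
                        name_norm = character(), role_code = character(),
                        start_token = character(), start_precision = character())),
    bind("events", empty(report_id = character(), pt = character(),
                         pt_verbatim = character(), soc = character(),
                         event_token = character(), event_precision = character(),
                         outcome = character())),
    bind("outcomes", empty(report_id = character(), code = character())),
    bind("indications", empty(report_id = character(), term = character())),
    bind("therapy", empty(report_id = character(), start_token = character(),
                          start_precision = character())),
    source_db
  )
  x
}
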