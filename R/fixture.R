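#' Deterministic hand-auditable mini-dataset
#'
#' Twenty cases in the FAERS dialect, constructed so that every ingest
#' branch fires exactly once and the retained set can be checked by hand:
#' a duplicate case pair resolved by receipt date (case 201), a
#' receipt-date tie resolved by the higher primary id (case 202), a deleted
#' case (203), a report where the target drug is concomitant only (204),
#' a report without the target drug (205), a Japan-country report (206),
#' a month-precision event date (207), an event predating therapy (208)
#' and a report with no therapy start at all (209). Cases 210-220 carry
#' clean onset intervals of 0, 5, 9, 14, 20, 28, 35, 60, 76, 100 and 400
#' days.
#'
#' @param out_dir optional directory to write the files to (FAERS-dialect
#'   text plus `meddra_map.tsv` and `lexicon.txt`).
#' @return list with `faers` (tables + `deleted`), `meddra_map`, `lexicon`
#'   and `expected` (the hand-computed retained ids, counts and onset
#'   intervals the pipeline must reproduce).
#' @export
fixture_small <- function(out_dir = NULL) {
  dt <- data.table::data.table
  demo <- dt(
    PRIMARYID = c("101", "121", "102", "122", as.character(103:120)),
    CASEID = c("201", "201", "202", "202", as.character(203:220)),
    FDA_DT = c("20200101", "20200301",       # dup pair: keep 121
               "20200101", "20200101",       # tie: keep 122
               rep("20200601", 18)),
    EVENT_DT = c("20200129", "20200129", "20200111", "20200111",
                 "20200105",                  # 203 (deleted anyway)
                 "20200105", "20200105",      # 204, 205
                 "20200105",                  # 206 (JP)
                 "202003",                    # 207 month precision
                 "20200101",                  # 208 negative
                 "20200110",                  # 209 start missing
                 "20200101", "20200106", "20200110", "20200115",
                 "20200121", "20200129", "20200205", "20200301",
                 "20200317", "20200410", "20220205"), # 210-220
    SEX = c("M", "M", "F", "F", "M", "F", "M", "M", "F", "M", "F",
            "M", "F", "M", "F", "M", "F", "M", "", "M", "F", "M"),
    AGE = c("60", "60", "70", "70", "55", "40", "66", "50", "71", "45",
            "80", "63", "59", "47", "68", "72", "33", "61", "", "58",
            "64", "69"),
    AGE_COD = "YR",
    WT = c("70", "70", "55", "55", "80", "", "102", "60", "", "75", "48",
           "66", "", "90", "58", "77", "", "81", "", "69", "73", "110"),
    WT_COD = "KG",
    REPORTER_COUNTRY = c("US", "US", "FR", "FR", "US", "US", "IT", "JP",
                         "US", "GB", "CA", "US", "FR", "US", "IT", "US",
                         "GB", "US", "FR", "US", "CA", "US"),
    OCCR_COUNTRY = c("US", "US", "FR", "FR", "US", "US", "IT", "JP",
                     "US", "GB", "CA", "US", "FR", "US", "IT", "US",
                     "GB", "US", "FR", "US", "CA", "US"))

  ps <- function(pid, cid, name, role = "PS", start = "") {
    dt(PRIMARYID = pid, CASEID = cid, DRUG_SEQ = "1", ROLE_COD = role,
       DRUGNAME = name, START_DT = start)
  }
  starts <- c("210" = "20200101", "211" = "20200101", "212" = "20200101",
              "213" = "20200101", "214" = "20200101", "215" = "20200101",
              "216" = "20200101", "217" = "20200101", "218" = "20200101",
              "219" = "20200101", "220" = "20210101")
  drug <- data.table::rbindlist(list(
    ps("101", "201", "IRINOTECAN"), ps("121", "201", "IRINOTECAN"),
    ps("102", "202", "IRINOTECAN HYDROCHLORIDE"),
    ps("122", "202", "IRINOTECAN HYDROCHLORIDE"),
    ps("103", "203", "IRINOTECAN"),
    ps("104", "204", "OXALIPLATIN"),            # 204: target only concomitant
    ps("104", "204", "IRINOTECAN", role = "C"),
    ps("105", "205", "PEMBROLIZUMAB"),          # 205: no target drug
    ps("106", "206", "CAMPTOSAR"),              # 206: JP, dropped by country
    ps("107", "207", "IRINOTECAN"),
    ps("108", "208", "IRINOTECAN"),
    ps("109", "209", "IRINOTECAN"),
    data.table::rbindlist(lapply(names(starts), function(cid) {
      pid <- as.character(as.integer(cid) - 100L)
      ps(pid, cid, "IRINOTECAN")
    })),
    # concomitant entries on two otherwise-clean reports
    ps("115", "215", "FLUOROURACIL", role = "C"),
    ps("118", "218", "BEVACIZUMAB", role = "SS")))

  re <- function(pid, cid, pt) dt(PRIMARYID = pid, CASEID = cid, PT = pt)
  reac <- data.table::rbindlist(list(
    re("101", "201", "Diarrhoea"), re("121", "201", "Diarrhoea"),
    re("102", "202", "Neutropenia"), re("122", "202", "Neutropenia"),
    re("103", "203", "Nausea"),
    re("104", "204", "Vomiting"), re("105", "205", "Nausea"),
    re("106", "206", "Diarrhoea"),
    re("107", "207", "Stomatitis"), re("108", "208", "Diarrhoea"),
    re("109", "209", "Anaemia"),
    re("110", "210", "Diarrhoea"), re("110", "210", "Nausea"),
    re("111", "211", "Neutropenia"), re("112", "212", "Diarrhoea"),
    re("113", "213", "Hiccups"), re("114", "214", "Vomiting"),
    re("115", "215", "Febrile neutropenia"), re("116", "216", "Diarrhoea"),
    re("117", "217", "Thrombocytopenia"), re("118", "218", "Hepatic failure"),
    re("119", "219", "Dehydration"), re("120", "220", "Neutropenia")))

  ther <- dt(PRIMARYID = c("101", "121", "102", "122", "103", "104", "105",
                           "106", "107", "108",
                           as.character(110:120)),
             CASEID = c("201", "201", "202", "202", "203", "204", "205",
                        "206", "207", "208", names(starts)),
             DSG_DRUG_SEQ = "1",
             START_DT = c("20200101", "20200101", "20200101", "20200101",
                          "20200101", "20200101", "20200101", "20200101",
                          "20200201", "20200110", unname(starts)),
             END_DT = "")

  outc <- dt(PRIMARYID = c("121", "122", "113", "118", "119", "110", "111"),
             CASEID = c("201", "202", "213", "218", "219", "210", "211"),
             OUTC_COD = c("HO", "DE", "OT", "DE", "HO", "OT", "HO"))
  indi <- dt(PRIMARYID = c("121", "122", "110", "111", "112"),
             CASEID = c("201", "202", "210", "211", "212"),
             INDI_PT = c("Colorectal cancer metastatic", "Colon cancer",
                         "Colorectal cancer metastatic", "Pancreatic carcinoma",
                         "Rectal cancer"))

  meddra_map <- dt(
    pt = normalize_term(c("Diarrhoea", "Neutropenia", "Nausea", "Vomiting",
                          "Stomatitis", "Anaemia", "Hiccups",
                          "Febrile neutropenia", "Thrombocytopenia",
                          "Hepatic failure", "Dehydration")),
    soc = c("Gastrointestinal disorders",
            "Blood and lymphatic system disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "Gastrointestinal disorders",
            "Blood and lymphatic system disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "Blood and lymphatic system disorders",
            "Blood and lymphatic system disorders",
            "Hepatobiliary disorders",
            "Metabolism and nutrition disorders"))
  lexicon <- c("IRINOTECAN", "IRINOTECAN HCL", "IRINOTECAN HYDROCHLORIDE",
               "CPT 11 IRINOTECAN", "CPT 11", "CAMPTOSAR", "CAMPTO")

  fx <- list(
    faers = list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc, indi = indi, deleted = "203"),
    meddra_map = meddra_map,
    lexicon = lexicon,
    expected = list(
      dedup_keep = c("121", "122", as.character(103:120)),
      retained_cases = c("201", "202", as.character(207:220)),
      n_retained = 16L,
      tto_included = c("201" = 28L, "202" = 10L, "210" = 0L, "211" = 5L,
                       "212" = 9L, "213" = 14L, "214" = 20L, "215" = 28L,
                       "216" = 35L, "217" = 60L, "218" = 76L, "219" = 100L,
                       "220" = 400L),
      tto_excluded = c("207" = "excluded_imprecise",
                       "208" = "excluded_negative",
                       "209" = "excluded_missing")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dollar <- function(tab, path) {
      lines <- c(paste(names(tab), collapse = "$"),
                 do.call(paste, c(lapply(tab, as.character), sep = "$")))
      writeLines(lines, file.path(out_dir, path))
    }
    dollar(demo, "DEMO.txt"); dollar(drug, "DRUG.txt")
    dollar(reac, "REAC.txt"); dollar(ther, "THER.txt")
    dollar(outc, "OUTC.txt"); dollar(indi, "INDI.txt")
    writeLines(fx$faers$deleted, file.path(out_dir, "DELETED.txt"))
    data.table::fwrite(meddra_map, file.path(out_dir, "meddra_map.tsv"),
                       sep = "\t")
    writeLines(lexicon, file.path(out_dir, "lexicon.txt"))
  }
  fx
}
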