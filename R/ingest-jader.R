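# JADER extract tables: comma-separated demo/drug/reac/hist files with
# Japanese column names, historically shipped in a legacy Japanese codepage.
# Files are decoded to UTF-8 up front (configurable encoding); undecodable
# bytes are a hard error naming the file and line.

jader_cols <- list(
  demo = c(case = "識別番号",        # 識別番号
           seq = "報告回数",          # 報告回数
           sex = "性別",                      # 性別
           age = "年齢",                      # 年齢
           weight = "体重",                   # 体重
           receipt = "報告年月日" # 報告年月日
  ),
  drug = c(case = "識別番号",
           role = "医薬品の関与",          # 医薬品の関与
           name = "医薬品（一般名）", # 医薬品（一般名）
           start = "投与開始日",               # 投与開始日
           end = "投与終了日"                  # 投与終了日
  ),
  reac = c(case = "識別番号",
           pt = "有害事象",                        # 有害事象
           event_date = "発現日",                      # 発現日
           outcome = "転帰"                                # 転帰
  ),
  hist = c(case = "識別番号",
           indication = "原疾患等"                 # 原疾患等
  )
)

# 被疑薬 / 併用薬 / 相互作用 -> PS / C / I
jader_role_map <- c("被疑薬" = "PS",
                    "併用薬" = "C",
                    "相互作用" = "I")

# 死亡 (death outcome term, used for fatality scoring)
jader_death_term <- "死亡"

read_jader_csv <- function(path, encoding) {
  stopifnot(file.exists(path))
  raw <- readBin(path, "raw", file.size(path))
  txt <- iconv(list(raw), from = encoding, to = "UTF-8")
  if (is.na(txt)) {
    # locate first undecodable line for the diagnostic
    lines <- suppressWarnings(
      strsplit(rawToChar(raw, multiple = FALSE), "\n", fixed = TRUE)[[1]])
    dec <- suppressWarnings(iconv(lines, from = encoding, to = "UTF-8"))
    bad <- which(is.na(dec))[1]
    stop(sprintf("undecodable bytes in %s under encoding %s (line %s)",
                 basename(path), encoding, ifelse(is.na(bad), "?", bad)))
  }
  data.table::fread(text = txt, sep = ",", header = TRUE,
                    colClasses = "character", encoding = "UTF-8")
}

#' Read one JADER-dialect file set
#'
#' Reads the comma-separated `demo`, `drug`, `reac` and `hist` tables
#' (files `demo*.csv` etc., matched case-insensitively) and maps the JADER
#' column vocabulary onto the shared row types used by the FAERS reader:
#' the case number acts as case id, the case number combined with the
#' report sequence acts as report id (the latest sequence is the current
#' version of a case), and the suspect-role vocabulary
#' (被疑薬/併用薬/相互作用) is
#' mapped to `PS`/`C`/`I`.
#'
#' @param dir directory containing the tables.
#' @param encoding source encoding; the historical default is `"CP932"`,
#'   generated fixtures use `"UTF-8"`.
#' @return list of `data.table`s `demo`, `drug`, `reac`, `hist` with
#'   harmonized column names (`case_id`, `report_seq`, `sex`, `age`,
#'   `weight`, `receipt`, `role_code`, `drug_name`, `start_token`,
#'   `pt`, `event_token`, `outcome`, `indication`).
#' @export
parse_jader_tables <- function(dir, encoding = "CP932") {
  stopifnot(dir.exists(dir))
  out <- list()
  for (stem in names(jader_cols)) {
    path <- list.files(dir, pattern = paste0("(?i)^", stem, ".*\\.csv$"),
                       full.names = TRUE)
    if (length(path) == 0L) {
      if (stem %in% c("demo", "drug", "reac")) stop("no ", stem, "*.csv in ", dir)
      out[[stem]] <- NULL
      next
    }
    dt <- read_jader_csv(sort(path)[1], encoding)
    cols <- jader_cols[[stem]]
    miss <- setdiff(unname(cols), names(dt))
    if (length(miss)) {
      stop(sprintf("JADER %s table missing column(s): %s",
                   stem, paste(miss, collapse = ", ")))
    }
    keep <- dt[, unname(cols), with = FALSE]
    data.table::setnames(keep, names(cols))
    data.table::setnames(keep, "case", "case_id")
    out[[stem]] <- keep
  }
  out$drug[, role_code := unname(jader_role_map[role])]
  out$drug[is.na(role_code), role_code := "C"]
  out
}

# JADER ages arrive as decade strings ("60歳代"); return the decade lower
# bound in years, or a plain numeric when given one.
jader_age_years <- function(x) {
  x <- trimws(as.character(x))
  dec <- regmatches(x, regexpr("^[0-9]+(?=歳代$)", x, perl = TRUE))
  out <- suppressWarnings(as.numeric(x))
  has_dec <- grepl("歳代$", x)
  out[has_dec] <- suppressWarnings(as.numeric(sub("歳代$", "", x[has_dec])))
  out
}

# JADER weights as decade-of-kg strings ("50kg代") or numerics.
jader_weight_kg <- function(x) {
  x <- trimws(as.character(x))
  suppressWarnings(as.numeric(sub("kg.*$", "", x)))
}
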