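# Synthetic spontaneous-report generator. Emits the same underlying report
# set in both the FAERS dialect ("$"-delimited DEMO/DRUG/REAC/THER/OUTC/INDI
# files plus a deleted-case list) and the JADER dialect (comma-separated
# demo/drug/reac/hist tables), together with the planted ground truth, so
# every pipeline stage is testable without external downloads.

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the structure of a 20-year single-drug extraction:
#' a mean of about 3.15 distinct preferred terms per report (truncated
#' geometric), a Zipf-like background term frequency profile, onset delays
#' drawn from a Weibull with shape 0.7 and scale 47 days (median 28 days,
#' a decreasing early-failure hazard), 5% duplicate case resubmissions,
#' 2% deleted cases, 20% missing and 10% imprecise therapy/event dates,
#' 2% negative onset intervals, and a country mix with a 5% Japan share
#' (so the Japan-exclusion rule is exercised).
#'
#' @param n_reports number of underlying cases.
#' @param seed mandatory RNG seed; generation is fully deterministic.
#' @param target_drug verbatim name of the drug under study.
#' @param n_background_drugs size of the rest of the drug vocabulary.
#' @param n_pts,n_socs event vocabulary size and its SOC partition
#'   (terms are assigned to SOCs round-robin).
#' @param target_share probability that a report's primary suspect is the
#'   target drug.
#' @param events_geom_p geometric parameter for the distinct-PT count per
#'   report (`k = min(1 + G, max_events)`, `G ~ Geom(p)`); the default
#'   1/3.15 gives a mean near 3.15.
#' @param max_events cap on distinct PTs per report.
#' @param signals `data.frame(pt, lambda)` of planted reporting-ratio
#'   signals for the target drug (`lambda = 1` elsewhere); an optional
#'   `death_prob` column raises the fatality rate of reports carrying the
#'   term.
#' @param duplicate_rate fraction of cases re-submitted with a later
#'   receipt date, higher primary id and perturbed demographics.
#' @param deleted_rate fraction of cases named on the deleted-case list.
#' @param date_missing_rate,date_imprecise_rate per-date probabilities of a
#'   blank token and of truncation to month or year precision.
#' @param negative_tto_rate fraction of reports whose event date is placed
#'   before the therapy start.
#' @param tto_shape,tto_scale Weibull onset-delay parameters (days).
#' @param country_mix named probability vector of reporter countries.
#' @param sex_mix,death_prob demographic mixes; `death_prob` is the
#'   baseline probability of a death outcome.
#' @param monotherapy_fraction fraction of target-drug reports with no
#'   concomitant medication.
#' @param year_range calendar window for therapy start dates.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 5000L,
                       seed,
                       target_drug = "IRINOTECAN",
                       n_background_drugs = 20L,
                       n_pts = 60L,
                       n_socs = 10L,
                       target_share = 0.15,
                       events_geom_p = 1 / 3.15,
                       max_events = 10L,
                       signals = data.frame(pt = character(),
                                            lambda = numeric()),
                       duplicate_rate = 0.05,
                       deleted_rate = 0.02,
                       date_missing_rate = 0.2,
                       date_imprecise_rate = 0.1,
                       negative_tto_rate = 0.02,
                       tto_shape = 0.7,
                       tto_scale = 47,
                       country_mix = c(US = 0.38, FR = 0.12, IT = 0.10,
                                       GB = 0.06, CA = 0.06, JP = 0.05,
                                       DE = 0.05, ES = 0.04, AU = 0.04,
                                       BR = 0.20),
                       sex_mix = c(M = 0.46, F = 0.34, U = 0.20),
                       death_prob = 0.15,
                       monotherapy_fraction = 0.3,
                       year_range = c(2004L, 2023L)) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  signals <- as.data.frame(signals, stringsAsFactors = FALSE)
  cfg <- list(n_reports = as.integer(n_reports), seed = as.integer(seed),
              target_drug = target_drug,
              n_background_drugs = as.integer(n_background_drugs),
              n_pts = as.integer(n_pts), n_socs = as.integer(n_socs),
              target_share = target_share, events_geom_p = events_geom_p,
              max_events = as.integer(max_events), signals = signals,
              duplicate_rate = duplicate_rate, deleted_rate = deleted_rate,
              date_missing_rate = date_missing_rate,
              date_imprecise_rate = date_imprecise_rate,
              negative_tto_rate = negative_tto_rate,
              tto_shape = tto_shape, tto_scale = tto_scale,
              country_mix = country_mix / sum(country_mix),
              sex_mix = sex_mix / sum(sex_mix),
              death_prob = death_prob,
              monotherapy_fraction = monotherapy_fraction,
              year_range = year_range)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$target_share, cfg$events_geom_p, cfg$duplicate_rate,
             cfg$deleted_rate, cfg$date_missing_rate,
             cfg$date_imprecise_rate, cfg$negative_tto_rate,
             cfg$death_prob, cfg$monotherapy_fraction)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must be in [0, 1]")
  if (cfg$n_reports < 1L) stop("sim_config: n_reports must be positive")
  if (cfg$tto_shape <= 0 || cfg$tto_scale <= 0) {
    stop("sim_config: Weibull onset parameters must be positive")
  }
  sig <- cfg$signals
  if (nrow(sig)) {
    if (!all(c("pt", "lambda") %in% names(sig))) {
      stop("sim_config: signals need columns pt, lambda")
    }
    if (any(sig$lambda <= 0)) stop("sim_config: planted lambda must be > 0")
    pts <- sim_pt_names(cfg)
    if (!all(sig$pt %in% pts)) {
      stop("sim_config: planted signal PT not in the event vocabulary")
    }
    if ("death_prob" %in% names(sig) &&
        any(sig$death_prob < 0 | sig$death_prob > 1)) {
      stop("sim_config: per-term death_prob must be in [0, 1]")
    }
  }
  invisible(cfg)
}

sim_pt_names <- function(cfg) sprintf("pt_%03d", seq_len(cfg$n_pts))
sim_soc_names <- function(cfg) {
  sprintf("soc_%02d", rep_len(seq_len(cfg$n_socs), cfg$n_pts))
}
sim_drug_names <- function(cfg) {
  c(cfg$target_drug, sprintf("DRUG_%03d", seq_len(cfg$n_background_drugs)))
}

# Zipf-like background probabilities over the PT vocabulary.
sim_pt_probs <- function(cfg) {
  p <- 1 / seq_len(cfg$n_pts)
  p / sum(p)
}

# lambda-weighted PT probabilities for target-drug reports.
sim_target_probs <- function(cfg) {
  p <- sim_pt_probs(cfg)
  names(p) <- sim_pt_names(cfg)
  if (nrow(cfg$signals)) {
    idx <- match(cfg$signals$pt, names(p))
    p[idx] <- p[idx] * cfg$signals$lambda
  }
  p / sum(p)
}

# P(K = k) for the truncated-geometric distinct-PT count.
sim_k_pmf <- function(cfg) {
  p <- cfg$events_geom_p
  k <- seq_len(cfg$max_events)
  pmf <- (1 - p)^(k - 1) * p
  pmf[cfg$max_events] <- (1 - p)^(cfg$max_events - 1)
  pmf
}

# P(term appears in a report) given per-draw probability w: draws are with
# replacement and deduplicated, so P = sum_k P(K=k) (1 - (1-w)^k).
sim_inclusion_prob <- function(cfg, w) {
  pmf <- sim_k_pmf(cfg)
  k <- seq_along(pmf)
  vapply(w, function(wi) sum(pmf * (1 - (1 - wi)^k)), numeric(1))
}

date_to_token <- function(d) format(d, "%Y%m%d")

# Apply missingness then imprecision to day-precision tokens.
degrade_tokens <- function(tok, missing_rate, imprecise_rate) {
  n <- length(tok)
  u <- stats::runif(n)
  tok[u < missing_rate] <- ""
  v <- stats::runif(n)
  impre <- u >= missing_rate & v < imprecise_rate & nzchar(tok)
  half <- stats::runif(n) < 0.5
  tok[impre & half] <- substr(tok[impre & half], 1, 6)   # month precision
  tok[impre & !half] <- substr(tok[impre & !half], 1, 4) # year precision
  tok
}

#' Generate a synthetic report database with ground truth
#'
#' Draws `n_reports` cases under the configuration, renders them in the
#' FAERS dialect and the JADER dialect (same underlying truth, so
#' cross-database overlap is testable with known shared signals), and
#' returns the planted ground truth: per planted drug-event pair the true
#' reporting ratio and expected count among clean analyzable target
#' reports, and per report the canonical case id, duplicate link and true
#' onset interval. Output is byte-identical for identical seeds.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, the FAERS-style files,
#'   JADER-style CSVs (UTF-8) and ground-truth TSVs are written there.
#' @return list with elements `faers` (named list of data.tables in FAERS
#'   column vocabulary plus `deleted`), `jader` (JADER column vocabulary),
#'   `truth` (list `signals`, `reports`), and `config`.
#' @export
simulate_reports <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reports
  pts <- sim_pt_names(cfg)
  socs <- sim_soc_names(cfg)
  drugs <- sim_drug_names(cfg)

  ## --- case frame -------------------------------------------------------
  rid <- seq_len(n)
  primaryid <- as.character(10000000 + rid * 10)
  caseid <- as.character(20000000 + rid)
  suspect <- ifelse(stats::runif(n) < cfg$target_share, drugs[1],
                    sample(drugs[-1], n, replace = TRUE))
  is_target <- suspect == drugs[1]
  country <- sample(names(cfg$country_mix), n, replace = TRUE,
                    prob = cfg$country_mix)
  sex <- sample(names(cfg$sex_mix), n, replace = TRUE, prob = cfg$sex_mix)
  age <- round(pmax(18, pmin(95, stats::rnorm(n, 62, 13))))
  age[stats::runif(n) < 0.25] <- NA
  wt <- round(pmax(35, pmin(140, stats::rnorm(n, 74, 16))), 1)
  wt[stats::runif(n) < 0.6] <- NA

  ## --- events: k distinct PTs per report --------------------------------
  k <- pmin(1L + stats::rgeom(n, cfg$events_geom_p), cfg$max_events)
  p_bg <- sim_pt_probs(cfg)
  p_tg <- sim_target_probs(cfg)
  draw_events <- function(idx, prob) {
    tot <- sum(k[idx])
    if (tot == 0L) return(NULL)
    data.table::data.table(rid = rep(idx, k[idx]),
                           pt = sample(pts, tot, replace = TRUE, prob = prob))
  }
  ev <- data.table::rbindlist(list(draw_events(which(is_target), p_tg),
                                   draw_events(which(!is_target), p_bg)))
  ev <- unique(ev)
  data.table::setorder(ev, rid, pt)

  ## --- dates and onset --------------------------------------------------
  origin <- as.Date(sprintf("%d-01-01", cfg$year_range[1]))
  span <- as.integer(as.Date(sprintf("%d-12-31", cfg$year_range[2])) - origin)
  start_date <- origin + sample.int(span, n, replace = TRUE)
  delay <- round(stats::rweibull(n, cfg$tto_shape, cfg$tto_scale))
  neg <- stats::runif(n) < cfg$negative_tto_rate
  delay[neg] <- -sample.int(30, sum(neg), replace = TRUE)
  event_date <- start_date + delay
  fda_dt <- event_date + sample.int(300, n, replace = TRUE) + 30L

  start_tok <- degrade_tokens(date_to_token(start_date),
                              cfg$date_missing_rate, cfg$date_imprecise_rate)
  event_tok <- degrade_tokens(date_to_token(event_date),
                              cfg$date_missing_rate, cfg$date_imprecise_rate)

  ## --- outcomes ---------------------------------------------------------
  p_death <- rep(cfg$death_prob, n)
  if (nrow(cfg$signals) && "death_prob" %in% names(cfg$signals)) {
    for (j in seq_len(nrow(cfg$signals))) {
      dp <- cfg$signals$death_prob[j]
      if (is.na(dp)) next
      hit <- ev[pt == cfg$signals$pt[j], unique(rid)]
      p_death[hit] <- pmax(p_death[hit], dp)
    }
  }
  died <- stats::runif(n) < p_death
  other_codes <- c("OT", "HO", "LT", "DS", "RI", "CA")
  outc <- ifelse(died, "DE",
                 sample(other_codes, n, replace = TRUE,
                        prob = c(0.45, 0.38, 0.08, 0.05, 0.03, 0.01)))

  ## --- concomitant medication ------------------------------------------
  mono <- stats::runif(n) < cfg$monotherapy_fraction
  n_conc <- ifelse(mono, 0L, sample(0:3, n, replace = TRUE,
                                    prob = c(0.25, 0.4, 0.25, 0.1)))
  conc_idx <- rep(rid, n_conc)
  conc <- if (length(conc_idx)) {
    data.table::data.table(
      rid = conc_idx,
      name = sample(drugs[-1], length(conc_idx), replace = TRUE),
      role = sample(c("C", "SS", "I"), length(conc_idx), replace = TRUE,
                    prob = c(0.7, 0.2, 0.1)))
  } else data.table::data.table(rid = integer(), name = character(),
                                role = character())
  # a concomitant entry never duplicates the suspect drug of its report
  conc <- conc[name != suspect[rid]]

  indi_vocab <- c("colorectal cancer metastatic", "pancreatic carcinoma",
                  "colon cancer", "colorectal cancer", "colon cancer metastatic",
                  "rectal cancer", "gastric cancer", "ovarian cancer")
  indication <- sample(indi_vocab, n, replace = TRUE,
                       prob = c(0.25, 0.15, 0.12, 0.10, 0.06, 0.12, 0.10, 0.10))

  ## --- duplicates and deletions ----------------------------------------
  dup_of <- which(stats::runif(n) < cfg$duplicate_rate)
  dup_primaryid <- as.character(as.numeric(primaryid[dup_of]) + 1L)
  dup_fda <- fda_dt[dup_of] + sample.int(120, length(dup_of), replace = TRUE)
  deleted <- caseid[stats::runif(n) < cfg$deleted_rate]

  ## --- FAERS dialect ----------------------------------------------------
  demo <- data.table::data.table(
    PRIMARYID = primaryid, CASEID = caseid,
    FDA_DT = date_to_token(fda_dt), EVENT_DT = event_tok,
    SEX = ifelse(sex == "U", "", sex),
    AGE = ifelse(is.na(age), "", as.character(age)), AGE_COD = "YR",
    WT = ifelse(is.na(wt), "", as.character(wt)), WT_COD = "KG",
    REPORTER_COUNTRY = country, OCCR_COUNTRY = country)
  dup_demo <- demo[dup_of]
  dup_demo[, `:=`(PRIMARYID = dup_primaryid, FDA_DT = date_to_token(dup_fda),
                  SEX = "")]  # perturbed demographics on the resubmission
  demo_all <- rbind(demo, dup_demo)

  drug_rows <- data.table::data.table(
    rid = c(rid, conc$rid),
    DRUGNAME = c(suspect, conc$name),
    ROLE_COD = c(rep("PS", n), conc$role),
    START_DT = c(start_tok, rep("", nrow(conc))))
  data.table::setorder(drug_rows, rid)
  expand_dialect <- function(tab) {
    # render child rows for originals and re-emit them under duplicate ids
    base <- data.table::copy(tab)
    base[, `:=`(PRIMARYID = primaryid[rid], CASEID = caseid[rid])]
    dups <- tab[rid %in% dup_of]
    if (nrow(dups)) {
      m <- match(dups$rid, dup_of)
      dups[, `:=`(PRIMARYID = dup_primaryid[m], CASEID = caseid[dup_of][m])]
    }
    out <- rbind(base, if (nrow(dups)) dups else NULL)
    out[, rid := NULL]
    data.table::setcolorder(out, c("PRIMARYID", "CASEID"))
    out[]
  }
  drug_f <- expand_dialect(data.table::copy(drug_rows))
  drug_f[, DRUG_SEQ := seq_len(.N), by = PRIMARYID]
  reac_f <- expand_dialect(ev[, .(rid, PT = pt)])
  ther_f <- expand_dialect(data.table::data.table(rid = rid,
                                                  START_DT = start_tok,
                                                  END_DT = ""))
  outc_f <- expand_dialect(data.table::data.table(rid = rid, OUTC_COD = outc))
  indi_f <- expand_dialect(data.table::data.table(rid = rid,
                                                  INDI_PT = indication))
  faers <- list(demo = demo_all, drug = drug_f, reac = reac_f,
                ther = ther_f, outc = outc_f, indi = indi_f,
                deleted = deleted)

  ## --- JADER dialect (same truth) ---------------------------------------
  slash <- function(tok) {
    ifelse(nchar(tok) == 8,
           paste(substr(tok, 1, 4), substr(tok, 5, 6), substr(tok, 7, 8),
                 sep = "/"),
           ifelse(nchar(tok) == 6,
                  paste(substr(tok, 1, 4), substr(tok, 5, 6), sep = "/"), tok))
  }
  jp_sex <- c(M = "男性", F = "女性", U = "")
  jp_name <- function(x) ifelse(x == cfg$target_drug, "イリノテカン", x)
  jp_role <- c(PS = "被疑薬", C = "併用薬", SS = "併用薬",
               I = "相互作用")
  seq_no <- rep(1L, n)
  jdemo <- data.table::data.table(
    case = caseid, seq = as.character(seq_no),
    sex = unname(jp_sex[sex]),
    age = ifelse(is.na(age), "", sprintf("%d歳代", (age %/% 10) * 10)),
    weight = ifelse(is.na(wt), "", sprintf("%dkg代", (as.integer(wt) %/% 10) * 10)),
    receipt = date_to_token(fda_dt))
  jdrug <- data.table::data.table(
    case = caseid[drug_rows$rid],
    role = unname(jp_role[drug_rows$ROLE_COD]),
    name = jp_name(drug_rows$DRUGNAME),
    start = slash(drug_rows$START_DT),
    end = "")
  jp_outcome <- ifelse(died, "死亡",
                       sample(c("回復", "軽快", "未回復", "不明"),
                              n, replace = TRUE,
                              prob = c(0.45, 0.3, 0.15, 0.1)))
  jreac <- data.table::data.table(
    case = caseid[ev$rid], pt = ev$pt,
    event_date = slash(event_tok[ev$rid]),
    outcome = jp_outcome[ev$rid])
  jhist <- data.table::data.table(case = caseid, indication = indication)
  jader <- list(demo = jdemo, drug = jdrug, reac = jreac, hist = jhist)

  ## --- ground truth -----------------------------------------------------
  clean <- !(caseid %in% deleted) & country != "JP"
  clean_target <- which(clean & is_target)
  lam <- rep(1, cfg$n_pts)
  if (nrow(cfg$signals)) {
    lam[match(cfg$signals$pt, pts)] <- cfg$signals$lambda
  }
  truth_signals <- data.table::data.table(
    drug = drugs[1], pt = pts, soc = socs, lambda = lam,
    p_target = as.numeric(sim_target_probs(cfg)),
    expected_a = length(clean_target) *
      sim_inclusion_prob(cfg, as.numeric(sim_target_probs(cfg))),
    n_clean_target = length(clean_target))
  truth_reports <- data.table::data.table(
    primaryid = primaryid, caseid = caseid, suspect_drug = suspect,
    is_target = is_target, country = country,
    deleted = caseid %in% deleted,
    duplicated = rid %in% dup_of,
    duplicate_primaryid = NA_character_,
    true_tto = as.integer(delay), died = died)
  truth_reports[match(dup_of, rid), duplicate_primaryid := dup_primaryid]

  out <- list(faers = faers, jader = jader,
              truth = list(signals = truth_signals, reports = truth_reports),
              config = cfg)
  if (!is.null(out_dir)) write_sim(out, out_dir)
  out
}

# Write a simulated database to disk in both dialects.
write_sim <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dollar <- function(dt, path) {
    lines <- c(paste(names(dt), collapse = "$"),
               do.call(paste, c(lapply(dt, as.character), sep = "$")))
    writeLines(lines, file.path(out_dir, path))
  }
  dollar(sim$faers$demo, "DEMO.txt")
  dollar(sim$faers$drug, "DRUG.txt")
  dollar(sim$faers$reac, "REAC.txt")
  dollar(sim$faers$ther, "THER.txt")
  dollar(sim$faers$outc, "OUTC.txt")
  dollar(sim$faers$indi, "INDI.txt")
  writeLines(sim$faers$deleted, file.path(out_dir, "DELETED.txt"))
  jdir <- file.path(out_dir, "jader")
  dir.create(jdir, showWarnings = FALSE)
  wj <- function(dt, stem) {
    out <- data.table::copy(dt)
    cols <- jader_cols[[stem]]
    data.table::setnames(out, names(cols), unname(cols),
                         skip_absent = TRUE)
    data.table::fwrite(out, file.path(jdir, paste0(stem, ".csv")))
  }
  wj(sim$jader$demo, "demo")
  wj(sim$jader$drug, "drug")
  wj(sim$jader$reac, "reac")
  wj(sim$jader$hist, "hist")
  data.table::fwrite(sim$truth$signals, file.path(out_dir, "truth_signals.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$reports, file.path(out_dir, "truth_reports.tsv"),
                     sep = "\t")
  invisible(out_dir)
}

#' PT->SOC map of the synthetic event vocabulary
#' @param cfg a [sim_config()].
#' @return `data.table(pt, soc)` usable with [map_events()].
#' @export
sim_meddra_map <- function(cfg) {
  data.table::data.table(pt = normalize_term(sim_pt_names(cfg)),
                         soc = sim_soc_names(cfg))
}
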