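# pvsignal

Disproportionality signal detection for spontaneous adverse-event report
databases.

Post-marketing drug safety relies on spontaneous reporting systems (SRS)
such as the U.S. FDA Adverse Event Reporting System (FAERS) and the
Japanese Adverse Drug Event Report database (JADER). `pvsignal` implements
the complete analysis pipeline that pharmacovigilance studies run on these
databases — here configured for irinotecan, a topoisomerase-I-inhibitor
chemotherapeutic, but applicable to any target drug:

1. **Ingest and clean**: read FAERS quarterly `$`-delimited ASCII extracts
   and JADER CSV tables, deduplicate case versions (latest `FDA_DT`, ties
   broken by the higher `PRIMARYID`), drop deleted cases, keep reports
   where the target drug is the *primary suspect* (PS), exclude a country
   (Japan from the FAERS stream, to avoid double-counting against JADER),
   and code events to MedDRA preferred terms (PT) and system organ classes
   (SOC) via a user-supplied mapping table.
2. **Contingency tables**: for each PT and SOC, the 2×2 table
   (`a` drug∧event, `b` drug∧other events, `c` other drugs∧event,
   `d` neither), counted at the drug–event-pair level.
3. **Four disproportionality statistics** with their signal thresholds:

   | method | statistic | threshold |
   |---|---|---|
   | ROR | `ad/bc`, Woolf 95% CI | `a ≥ 3` and CI lower bound > 1 |
   | PRR | `[a/(a+b)]/[c/(c+d)]`, Pearson χ² | `a ≥ 3`, PRR ≥ 2, χ² ≥ 4 |
   | BCPNN | information component `IC = log2 O/E` (Bayesian shrinkage, Bate 1998 closed form) | `IC025 > 0` |
   | MGPS | `EBGM = 2^E[log2 λ]` under a DuMouchel gamma-mixture empirical-Bayes prior | `EBGM05 > 2` |

   A **positive signal** must satisfy all four simultaneously.
4. **Classification**: expectedness against a label-term list,
   cross-database signal overlap, a SOC-composition χ² comparison, and the
   0–8 clinical priority score (reporting rate, signal stability across
   algorithms, case fatality, IME/DME relevance; totals 0–2/3–5/6–8 map to
   low/medium/high priority).
5. **Time to onset (TTO)**: days from therapy start to event, excluding
   missing, imprecise (non-day-precision) and negative intervals; median /
   IQR, 30-day histogram, and a Weibull maximum-likelihood fit whose shape
   parameter β classifies the hazard (CI upper bound < 1 → *early
   failure*, i.e. decreasing hazard).
6. **Synthetic data**: a fully seeded report generator that emits the same
   ground truth in both the FAERS and JADER dialects, with planted
   reporting-ratio signals, duplicate resubmissions, deleted cases,
   configurable date missingness/imprecision and Weibull onset delays —
   so every stage is testable offline with known truth.

## Worked example

Simulate a 5,000-report database with two planted signals (reporting
ratios 10 and 5), run the whole pipeline, and inspect the positive
signals:

```r
library(pvsignal)
cfg <- sim_config(n_reports = 5000, seed = 42,
                  signals = data.frame(pt = c("pt_010", "pt_030"),
                                       lambda = c(10, 5)))
dir <- tempfile(); sim <- simulate_reports(cfg, out_dir = dir)

res <- run_pipeline(faers_dir = dir, lexicon = cfg$target_drug,
                    meddra_map = sim_meddra_map(cfg),
                    label_terms = "pt_010", ime_terms = "pt_030",
                    out_dir = file.path(dir, "out"), seed = 1)

m <- res$faers$metrics_pt
m[m$positive == TRUE, c("term", "a", "ror", "prr", "chi2", "ic025",
                        "ebgm05", "unexpected", "priority_total",
                        "priority_category")]
#>      term     a   ror   prr  chi2 ic025 ebgm05 unexpected priority_total priority_category
#> 1: pt_010   317  8.41  7.27   741  1.62   3.19      FALSE              4            medium
#> 2: pt_030    70  4.80  4.67   107  1.08   2.20       TRUE              4            medium

res$faers$weibull
#> <weibull_fit> n=376 scale=54.2 d shape=0.696 (95% CI 0.645-0.753) -> early_failure

res$faers$tto_summary$bins[1:3]
#>       bin     n   pct
#> 1:   0-30   187  49.7
#> 2:  31-60    61  16.2
#> 3:  61-90    40  10.6
```

Exactly the two planted terms come out positive: `pt_010` is on the label
(expected) while `pt_030` is an unexpected signal on the IME list. The
onset fit recovers the generator's decreasing-hazard Weibull (true shape
0.7) and classifies it as early failure. `run_pipeline()` also writes the
demographics, SOC/PT signal, priority, overlap and TTO tables as TSV plus
a `manifest.json` with the per-stage report counts (the conservation
ledger), under `out/`.

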