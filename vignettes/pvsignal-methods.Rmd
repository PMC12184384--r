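---
title: "Methods: disproportionality signal detection in spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems collect voluntary adverse drug event (ADE)
reports. They have no denominator of exposed patients, so risk cannot be
estimated directly; instead, *disproportionality analysis* asks whether a
drug–event pair is reported more often than the database background would
predict. `pvsignal` implements this for the two major systems' file
dialects — FAERS (quarterly `$`-delimited ASCII) and JADER (CSV with
Japanese column vocabulary) — with irinotecan as the shipped example
target drug.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, what the synthetic generator does and
does not emulate, and the package's known limitations.

## Ingestion model

A *case* may be resubmitted across quarters. Deduplication follows the
FDA-recommended rule: among rows sharing a `CASEID`, keep the most recent
`FDA_DT`; on ties, the higher `PRIMARYID` (numeric comparison when both
ids parse as integers, else lexicographic — deterministic either way). A
missing `FDA_DT` sorts as minus infinity, so any dated version beats an
undated one. Quarterly deleted-case lists are then applied.

Report-level filters:

* **Primary suspect**: a report is retained only if a lexicon drug name
  appears with role code `PS`. Matching is exact after trimming,
  whitespace collapse and case folding — no substring matching, which
  would wrongly capture combination products. The lexicon is a plain-text
  config file so users can widen it.
* **Country exclusion**: FAERS contains Japanese reports; excluding
  `JP` prevents double counting against JADER. The reporter-country field
  is used by default (the occurrence country is selectable); FAERS does
  not document which field such analyses use, and the reporter country is
  the more complete of the two. A blank country is *retained* — unknown
  is not the excluded country.
* **MedDRA coding**: events are annotated with their system organ class
  through a user-supplied PT→SOC table (the licensed MedDRA dictionary
  cannot be redistributed; `inst/extdata/meddra_map_synthetic.tsv` is an
  illustrative stand-in). Terms absent from the map are carried with
  `soc = "UNMAPPED"` rather than dropped.

Every filter records its drop count in a conservation ledger carried on
the report object and surfaced in the pipeline manifest: retained plus
per-rule drops always equals the input count.

JADER specifics: files are decoded from a configurable legacy codepage
(default CP932) to UTF-8 before parsing; the suspect-role vocabulary
(被疑薬/併用薬/相互作用) maps to `PS`/`C`/`I`; decade-coded ages
("60歳代") enter the 20–70 / >70 year bands by their decade lower bound.
Outcome percentages divide by the outcome-entry total in JADER (outcomes
are recorded per reaction entry there) but by the report count in FAERS —
both conventions are computed, fixed per database to match how each
system's tables are conventionally presented.

## Contingency counting

The counting unit is the **drug–event pair**: each distinct PT in a
report contributes one count, a PT repeated within a report counts once,
and a report with k distinct PTs adds k to the drug's event total. This
matches the convention under which a database's PT total (tens of
thousands) exceeds its report total by a factor of ~3. Terms never seen
with the target drug (`a = 0`) yield no table: no estimator is defined
there and the case-count thresholds would exclude them regardless.
Tables with a zero margin are flagged degenerate and excluded from
estimation rather than continuity-corrected.

## The four estimators

With cells `a, b, c, d` and `N` their sum:

* **ROR** `= ad/bc` with the Woolf interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Any zero cell → not estimable.
* **PRR** `= [a/(a+b)]/[c/(c+d)]` with the uncorrected Pearson
  `χ² = N(ad−bc)²/[(a+b)(c+d)(a+c)(b+d)]` on 1 d.f. The shortcut equals
  the `Σ(O−E)²/E` expansion to 1e-9 (verified on 1,000 random tables).
* **BCPNN IC**: the Bate et al. (1998) closed-form posterior with the
  standard hyperparameters `α = β = 2`, `α₁ = β₁ = 1`, `γ₁₁ = 1` and
  `γ = γ₁₁(N+α)(N+β)/((a+b+α₁)(a+c+β₁))`, which centres the prior on
  independence. `IC025 = E(IC) − 2√V(IC)`. The priors regularize zero
  cells, so every table is estimable.
* **MGPS EBGM**: counts are modelled as `a ~ Poisson(λE)` with
  `E = (a+b)(a+c)/N` and a two-component gamma mixture prior on the
  relative reporting ratio λ. The five hyperparameters are fitted by
  maximizing the negative-binomial mixture marginal likelihood over **all
  drug–event cells of the database** (not only the target drug's), per
  database, by BFGS on an unconstrained transform (logit weight, log
  shapes/rates) from the classical DuMouchel start
  `(P=1/3, α₁=0.2, β₁=0.1, α₂=2, β₂=4)`, a flat start, and
  seed-controlled random starts; the best converged optimum wins.
  The posterior is again a gamma mixture; `EBGM = 2^{E[log₂λ|a]}` in
  closed form and `EBGM05` by bisection on the mixture CDF to 1e-8
  relative tolerance. Mixture evidence is combined in log space.

These are the canonical literature forms behind the symbols IC025 and
EBGM05 in published FAERS analyses; each threshold
(`a ≥ 3`; ROR CI low > 1; PRR ≥ 2 ∧ χ² ≥ 4; IC025 > 0; EBGM05 > 2) is
configurable via `default_thresholds()`. No stratification (age, sex,
year) is applied in the MGPS model — the unstratified model is the
documented default, and stratified MGPS is out of scope.

## Signal classification and priority

A term is a *positive signal* only when all four thresholds hold at once;
this intersection rule deliberately trades sensitivity for a low
false-positive rate. Positives absent from the label-term list are
*unexpected*. The clinical priority score sums four 0–2 criteria:

| criterion | 2 points | 1 point | 0 points |
|---|---|---|---|
| reporting rate (share of the drug's events) | >10% | 1–10% | <1% |
| stability (algorithms flagging) | ≥3 | exactly 2 | ≤1 |
| case fatality among the term's reports | >50% | 25–50% | <25% |
| relevance | DME | IME | neither |

Totals 0–2 / 3–5 / 6–8 map to low / medium / high priority. Two design
points deserve note. First, the published criteria table for the
stability row is internally inconsistent ("3/4 of 4, 2 of 3, 1 of 3");
we follow the accompanying prose — at least three algorithms for the top
score. Second, the fatality denominator is *reports containing the term*
(not event entries), with death identified by outcome code `DE` (FAERS)
or 死亡 (JADER); report-level is the standard reading. A term on both the
DME and IME lists scores as DME. The reporting-rate criterion uses the
PT's share of the drug's total PT events, matching how top-term
percentages are conventionally printed, rather than its share of reports.

## Time to onset

TTO is the day difference between the earliest day-precision therapy
start date of the target drug and the earliest day-precision event date.
Records are excluded — with the reason conserved — when either date is
absent (`excluded_missing`), present only at month/year precision
(`excluded_imprecise`), or when the event precedes therapy
(`excluded_negative`). Quantiles use linear interpolation between order
statistics (R type 7), so the median/IQR are reproducible bit-for-bit.
The histogram uses 30-day bins (0–30, 31–60, …, >360); same-day onsets
fall in the first bin.

The Weibull fit maximizes the likelihood in scale α / shape β via
`fitdistrplus`, started deterministically from a log-scale
method-of-moments point (`sd(log x) = π/(√6·β)`). Same-day onsets are
shifted to 0.5 day (configurable) because the likelihood needs positive
support. The 95% CI for β is computed on the log scale from the
observed-information standard error and exponentiated, guaranteeing
positive bounds. The hazard class follows the CI against 1: upper < 1 →
early failure (decreasing hazard); lower > 1 → wear-out; otherwise
random. Degenerate inputs (all values equal, or n < 10) are rejected with
an informative error. Per-PT TTO stratification and interval-censoring
models are out of scope (pooled TTO only).

## The synthetic generator

`sim_config()` / `simulate_reports()` produce a seeded database rendered
in both dialects from one underlying truth, enabling cross-database
overlap tests with known shared signals. Defaults were fixed once to
emulate the structure of a 20-year single-drug extraction:

* distinct PTs per report: truncated geometric with mean ≈ 3.15,
  the events-per-report ratio implied by a PT total of ~35.7k over ~11.3k
  reports; events are drawn with replacement from a Zipf-like term
  profile and deduplicated within report, which keeps the per-term
  inclusion probability exactly computable for the ground truth;
* planted signals multiply a term's draw weight by λ for target-drug
  reports (weights renormalized); the ground truth stores the implied
  expected count among clean target reports;
* onset delays: Weibull, shape 0.7 and scale 47 days (median 28 days, a
  decreasing hazard — the pattern reported for irinotecan);
* imperfections: 5% duplicate resubmissions (later receipt date, higher
  primary id, perturbed demographics — so dedup correctness is
  observable), 2% deleted cases, 20% missing and 10% imprecise dates, 2%
  negative onsets, a 5% Japan share in the country mix (so the exclusion
  rule fires), 15% baseline fatal outcomes with optional per-term
  boosts, and a 30% monotherapy fraction.

Infeasible configurations (negative λ, probabilities outside [0,1],
signal terms outside the vocabulary) fail validation before any file is
written. Output is byte-identical for identical seeds.

What the generator does **not** emulate: real FAERS term frequencies and
drug co-prescription structure, reporting-rate secular trends,
indication–event confounding, and MedDRA hierarchy detail beyond a flat
PT→SOC assignment. Passing recovery tests therefore demonstrates that the
pipeline's statistics behave correctly under known truth — not that any
particular real-data signal is causal.

## Validation strategy and problem sizes

The shipped checks run three layers, sized to run comfortably on one CPU
(the whole suite in about two minutes):

1. closed-form worked examples — published percentages recomputed from
   their printed counts (`inst/extdata/irinotecan_counts.tsv`);
2. oracle equivalence on 1,000 random 2×2 tables — χ² shortcut vs the
   full expansion (1e-9), EBGM/EBGM05 vs numerical integration of the
   posterior mixture (1e-6), ROR/PRR/IC vs independent scalar
   re-derivations;
3. parameter recovery — an all-null 50,000-report simulation (four-way
   positive rate ≤ 5% of tested terms; observed 0%), a planted λ = 10
   signal recovered across 100 seeds at 5,000 reports each (≥ 90%
   required), Weibull shape recovery at n = 2,000 with CI coverage over
   200 replicates of n = 500, and the exact hand-computed retained set of
   the 20-case fixture (`fixture_small()`).

## Known limitations

* Drug-name matching is exact-after-normalization; misspellings and
  unlisted brand names in real data require widening the lexicon (no
  RxNorm linking or fuzzy matching).
* The MGPS prior fit assumes enough cells (≥ ~50 recommended) for the
  five-parameter mixture to be identifiable; tiny databases may converge
  to a boundary where both components coincide.
* SOC-level tables inherit the drug–event-pair counting unit, so a
  report contributes once per SOC touched, not once per PT within a SOC.
* The interchange format stores one report per line as JSON; it is a
  faithful round-trip of the cleaned object, not an archival dump of the
  raw files.
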