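Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous reporting system data in
    the FAERS and JADER dialects: report-level ingestion and deduplication,
    drug-event 2x2 contingency tables at the MedDRA preferred-term and
    system-organ-class levels, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio with chi-squared, the BCPNN
    information component, and the multi-item gamma Poisson shrinker EBGM)
    with signal thresholds, clinical priority scoring of positive signals,
    time-to-onset summaries with a Weibull hazard-shape test, and a synthetic
    report generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    fitdistrplus,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
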