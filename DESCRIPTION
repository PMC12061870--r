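Package: faersignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for disproportionality analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII format: ingestion and case-version
    deduplication, drug-name normalization against a synonym dictionary,
    MedDRA-style event mapping, 2x2 contingency construction overall and by
    sex/age stratum, four disproportionality statistics (reporting odds
    ratio, proportional reporting ratio, Bayesian confidence propagation
    information component, and multi-item gamma-Poisson shrinker empirical
    Bayes geometric mean) with positivity criteria and FDR-adjusted
    volcano payloads, and time-to-onset analysis with Weibull shape-based
    failure-type classification. A synthetic FAERS-format generator with
    planted reporting-rate ratios and Weibull onset times provides ground
    truth for validation, motivated by the thrombotic adverse-event
    profile of the five TNF-alpha blockers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    nortest
Config/testthat/edition: 3
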