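Package: pharmepi
Title: Pharmacovigilance Signal Detection and Claims-Based Cohort Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for drug-safety signal detection and pharmacoepidemiologic
    cohort analysis. Implements disproportionality analysis of spontaneous
    adverse-event reports (reporting odds ratio with Haldane-Anscombe
    correction, 95 percent confidence intervals and Z scores, volcano-plot
    tables), concomitant-drug confounder screening within a base drug class
    with cross-database enrichment of significant signals, and a new-user
    cohort pipeline for longitudinal claims data (run-in exclusion, index
    dating with systemic-route code lists, concomitant-use windows,
    propensity-score matching with caliper, covariate balance diagnostics,
    Kaplan-Meier estimation with daily numbers at risk, log-rank tests and
    Cox proportional-hazards models). Includes synthetic generators for
    spontaneous-report sets and insurance claims with known ground-truth
    effects, so every stage of the pipeline can be validated without access
    to proprietary databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
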