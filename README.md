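# pharmepi

Drug-safety signal detection and claims-based pharmacoepidemiology in R.

`pharmepi` is for pharmacoepidemiologists and drug-safety scientists who want
to run the two standard arms of a hypothesis-generating safety study end to
end, and to validate every stage on synthetic data with known ground truth
before touching a real database:

1. **Spontaneous-report disproportionality.** Ingest adverse-event report
   tables (FAERS/JADER/CVARD-style extracts), map raw drug names to unified
   generic names, deduplicate repeat submissions by case, and screen every
   drug — or every drug co-reported with a base class such as the
   fluoroquinolones — for disproportionate reporting of an outcome defined
   by an event-term query. Signals that are significant in the same
   direction in *every* database can be intersected
   (`cross_database_enrichment()`), the classic trick for separating real
   pharmacology from database-specific reporting artifacts.
2. **Claims-based new-user cohort analysis.** Turn longitudinal claims
   (enrollment spans, dated prescriptions with routes, dated diagnoses) into
   survival cohorts: run-in exclusion of prevalent cases and prior users,
   index dating on the first systemic prescription from a code list, a
   concomitant-use window around the index (default −7 to +30 days), 1:1
   nearest-neighbor propensity matching with a caliper, covariate balance
   diagnostics, and Kaplan–Meier / log-rank / Cox analysis with a daily
   number-at-risk table.

## The statistics at the core

For each drug the reports form a 2×2 table — `a` (drug & event), `b` (drug,
no event), `c` (no drug, event), `d` (neither). With the Haldane–Anscombe
correction (0.5 added to every cell, applied to all analyses so zero cells
stay finite), the reporting odds ratio and its Wald statistics are

    ROR = (a/b) / (c/d)
    SE  = sqrt(1/a + 1/b + 1/c + 1/d)
    95% CI = exp(ln ROR ± 1.96 · SE)
    Z   = ln(ROR) / SE

A drug is a significant signal when |Z| ≥ 1.96, equivalently when the 95%
CI excludes 1. The concomitant screen applies the same machinery inside the
sub-population of reports containing a base-class drug, so each concomitant
drug's ROR measures its association with the outcome *among base-drug
users*. The claims arm estimates hazard ratios by Cox partial likelihood
(Efron ties) on matched cohorts, with exact Clopper–Pearson intervals for
cumulative incidence proportions.

Both arms are backed by generators with known ground truth:
`simulate_reports()` draws report-level drug exposures and a logistic event
model whose odds multiply by per-drug and per-drug-pair odds ratios (so an
injected OR is exactly the estimand of the downstream ROR), and
`simulate_claims()` draws confounded exposure and a Poisson-process outcome
stream whose first post-index event is exactly exponential, so injected
hazard ratios are recovered without index-date selection bias.

## Worked example

Simulate a 50,000-report database in which levofloxacin has a true
drug–event odds ratio of 5 against a 5% baseline event probability, with
10% duplicate submissions, then screen it:

```r
library(pharmepi)

query <- event_query("tendinopathy", "tendinopathy")
cfg <- sr_sim_config(
  n_reports   = 50000,
  drug_catalog = c(levofloxacin = 0.05, aspirin = 0.10, metformin = 0.08),
  drug_event_or = c(levofloxacin = 5),
  baseline_event_prob = 0.05,
  duplicate_rate = 0.10,
  seed = 42)
sim <- simulate_reports(cfg, provenance = "SIM-SRS")
reports <- deduplicate_reports(sim$reports)
reports
#> <report_set> 50000 reports from SIM-SRS (deduplicated: TRUE, normalized: FALSE)
#>   distinct case ids: 50000

signals <- screen_drugs(reports, query, min_cases = 3)
signals
#> <signal_table> 3 drugs (|Z| >= 1.96: 1 up, 0 down)
#>           drug   a   ror ci_low ci_high      z n_reports
#> 1 levofloxacin 559 4.948  4.468    5.48 30.762      2597
#> 2      aspirin 316 1.054  0.935    1.19  0.862      4960
#> 3    metformin 233 0.955  0.833    1.10 -0.649      3980
```

The 5,000 injected duplicates are removed (50,000 distinct cases remain),
the injected drug recovers its odds ratio (ROR 4.95, 95% CI 4.47–5.48,
|Z| ≈ 31) while the null drugs sit at ROR ≈ 1, and `volcano_table(signals)`
gives the plot-ready `log10(ROR)` / |Z| / marker-size columns.

The claims arm follows the same pattern — see the methods vignette
(`vignettes/pharmepi-methods.Rmd`) for the full pipeline:
`simulate_claims()` → `apply_run_in()` → `assign_index()` →
`build_survival()` + `build_covariates()` → `fit_propensity()` →
`match_cohort()` → `balance_report()` → `cox_hr()` / `km_estimate()` /
`log_rank()` / `cumulative_incidence()`.

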