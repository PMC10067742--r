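---
title: "Methods: disproportionality screening and claims-based cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening and claims-based cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmepi)
```

This vignette explains the models and procedures behind `pharmepi`, the
design choices made where conventions genuinely differ between groups, and
what the bundled simulators do and do not emulate.

## 1. Disproportionality analysis of spontaneous reports

Spontaneous reporting systems collect voluntary adverse-event reports.
They have no denominators and no timelines, so nothing estimated from them
is an incidence; the usable signal is *disproportionality* — whether an
event is reported more often with a drug than the rest of the database
would predict. For a drug D and an event query Q the deduplicated,
name-normalized reports cross-tabulate as `a` (D and Q), `b` (D, not Q),
`c` (Q, not D), `d` (neither), and

$$\mathrm{ROR} = \frac{a/b}{c/d},\qquad
  \mathrm{SE} = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},\qquad
  Z = \frac{\ln \mathrm{ROR}}{\mathrm{SE}},$$

with the 95% interval $\exp(\ln\mathrm{ROR} \pm 1.96\,\mathrm{SE})$.

**Haldane–Anscombe correction.** 0.5 is added to *all four* cells before
computation, unconditionally — not only when a zero cell appears. Applying
it everywhere keeps estimates comparable across drugs and guarantees finite
ROR, CI and Z for any table. The uncorrected path is available but refuses
zero-cell tables with an explicit error rather than returning infinities.

**Significance.** $Z$ is the Wald statistic; $|Z| \ge 1.96$ is exactly
equivalent to the 95% CI excluding 1 (both use the same SE), and a
two-sided normal p-value is emitted for convenience. Volcano tables plot
$\log_{10}\mathrm{ROR}$ against $|Z|$ with per-drug report counts for
marker sizing. An optional Benjamini–Hochberg column is available but off
by default: disproportionality screens are conventionally read on
unadjusted Z with a case floor rather than a multiplicity correction.

**Case floor.** `min_cases = 3` on the pre-correction `a` cell is the
conventional pharmacovigilance floor for taking a signal seriously; it is
configurable everywhere it appears.

**Preprocessing contracts.** Deduplication keeps, per case id, the record
with the highest version, ties broken by the lexicographically greatest
report id — a simple, deterministic, testable strategy, documented as
swappable since real databases each have their own procedure. Drug-name
normalization is a case-insensitive raw→generic lookup; unmapped names are
*kept verbatim* by default because dropping them silently would shrink the
`c`/`d` denominators and bias every ROR. Event matching is exact string
equality on trimmed, case-folded terms: the query term list stands in for a
narrow-scope standardized MedDRA query, and no ontology traversal is
attempted.

## 2. Concomitant screening and cross-database enrichment

To ask whether a co-prescribed drug modifies a known drug–event
association, the same 2×2 machinery is applied *inside* the sub-population
of reports that contain at least one member of a base drug class (any-member
presence; spontaneous reports carry no dosing timeline, so "concomitant"
means co-listed on the same report). Each concomitant drug's ROR then
measures its association with the event among base-drug users; values below
1 flag candidate negative confounders or protective co-medications.

"Significantly decreased" is operationalized as the upper 95% bound below 1
(equivalently $Z \le -1.96$) at $\alpha = 0.05$. `cross_database_enrichment()`
intersects the drugs significant in the stated direction across every
supplied database (at least two, with distinct provenance labels) and
orders them by mean $\ln\mathrm{ROR}$, most extreme first. Only the
significance intersection is required — no additional effect-size floor —
and the returned set is monotone in both $\alpha$ and the number of
databases required.

## 3. The claims cohort pipeline

Claims data add the timeline that spontaneous reports lack. The pipeline
implements a first-prescription new-user design:

* **Run-in** (`run_in_days = 180`): patients with an outcome diagnosis, an
  exposure prescription or a concomitant-drug prescription during the first
  180 days of enrollment are excluded, as are patients enrolled for less
  than 180 days. This removes prevalent cases and prior users so observed
  events are incident and exposures are new. Run-in screening counts
  prescriptions of *any* route; the systemic-only rule is about what can
  define an index date or concomitant status, whereas a topical prescription
  during run-in still marks a prior user.
* **Index dating.** In the exposure design the index is the day of the
  first *systemic* exposure-code prescription at or after the run-in end;
  patients whose exposure prescriptions are all topical are never indexed.
  The concomitant group is defined by a systemic concomitant-code
  prescription within `[index − 7, index + 30]`, both boundaries inclusive.
  Repeat prescriptions after the first are ignored for index definition.
  In the older-adult design (age ≥ `min_age`), the concomitant group's
  index is the first systemic concomitant prescription after run-in; for
  the comparator the natural "first day at risk under observation" is the
  run-in end, so its clock starts there. That convention is a genuine
  design choice (nothing in the data dictates an unexposed patient's index)
  and is configurable by constructing the index map directly.
* **Survival records.** `time = min(first outcome day, disenrollment day,
  index + follow_up_days) − index`, `event = 1` iff the minimum is an
  outcome day. Outcomes on the index day give `time = 0, event = 1` and are
  kept. Follow-up defaults to 60 days — twice a 30-day risk period — in the
  exposure design and 180 days in the older-adult design. All intervals are
  half-open `[start, end)` on an integer-day axis; truncation happens here
  and nowhere else (the survival functions never re-censor).
* **Covariates** are assembled strictly from records on days before the
  index (`[index − lookback, index)`; a diagnosis on the index day never
  counts). The default lookback is 180 days, matching the run-in; `Inf`
  uses all pre-index history.

## 4. Propensity matching and balance

The propensity model is an additive logistic regression (a convex,
deterministic fit). Matching is greedy 1:1 nearest-neighbor without
replacement: exposed patients are visited in seeded-random order (the
literature leaves the order unspecified; seeding makes it reproducible) and
paired with the nearest unmatched comparator within the caliper. A "0.2
caliper width" is interpreted, per the usual convention, as 0.2 × SD of the
logit propensity score pooled over both arms; a raw probability-scale
caliper is available by flag. Optimal matching and IPTW are out of scope.

Balance is reported as standardized mean differences
$(\bar x_1 - \bar x_0)/s_\text{pooled}$ pre- and post-match, with
$s_\text{pooled}$ always taken from the pre-match sample so both numbers
share one scale; zero-variance covariates report SMD 0 with a flag.
Hypothesis tests on the matched sample follow covariate type: chi-square
for categorical flags, Wilcoxon rank-sum (default) or Welch's t for
continuous covariates such as age.

## 5. Survival analysis

Kaplan–Meier curves, the log-rank test and Cox models are computed by the
`survival` package (`survfit`, `survdiff`, `coxph`); `pharmepi` adds the
cohort semantics and a day-by-day number-at-risk table over
`[0, follow_up_days]` (subjects with `time ≥ t`), the format shown under
cumulative-incidence plots. Cox ties default to Efron (more accurate with
the heavy day-level ties of claims data); Breslow is available, under which
the two-group score test at β = 0 equals the log-rank statistic on tie-free
data — an identity the test suite asserts numerically. The group-only model
is the default after matching; covariate adjustment is available through the
`covariates` argument. Cumulative incidence proportions carry exact
Clopper–Pearson intervals. The test suite pins these routines to
hand-computed product-limit and O−E/V fixtures and to a closed-form score
equation solved by bisection, so the wrappers are verified against
independent arithmetic, not merely trusted.

## 6. The synthetic generators

Neither real reporting-system extracts nor commercial claims are
redistributable, so both generators exist as first-class, tested modules
whose defaults define the study conditions used throughout the tests.

**Reports.** Drug exposures are independent Bernoulli draws per report
(configurable prevalence per drug) plus a Poisson number of extra uniform
draws (`polypharmacy_rate`). The event indicator is logistic: baseline odds
multiplied by the OR of each present drug and of each present interacting
pair. Because the model is odds-multiplicative and the exposures
independent, an injected OR is exactly the estimand of the downstream ROR
when other drugs are null — making recovery tests exact in expectation.
Duplicates are injected as same-case-id copies with new report ids,
matching the deduplication contract. Defaults used in the validation runs:
50,000 reports for single-drug recovery (OR 5 at 5% prevalence), 15,000 per
database for the three-database interaction screen (interaction OR 0.3 on a
base drug with OR 3 at 20% prevalence), 5,000 for null calibration.

**Claims.** Enrollment spans have exponential lengths (mean 720 days)
inside a three-year window; binary confounders shift both exposure odds and
event hazard, and are materialized as diagnosis records early in enrollment
so the covariate builder can recover them; age enters both models
standardized. The outcome is a homogeneous Poisson process over the
enrollment span with rate
$\lambda_i = \lambda_0 \exp(\beta^\top x_i + \theta\,\text{exposed}_i)$.
The process (rather than a single latent time) is the load-bearing choice:
by independence of increments, the first event after *any* index day is
exponential with rate $\lambda_i$, so run-in exclusion and either index
convention introduce no selection bias into hazard-ratio recovery, and the
injected $e^\theta$ is the exact estimand of the post-index Cox fit. The
exposure multiplier applies from enrollment start, which the same
memorylessness property makes equivalent to applying it from the index.
Validation runs use 3,000-patient replicates (matching/bias-reduction,
50 replicates) and a single 8,000-patient cohort for the end-to-end run
(baseline hazard 1.5 × 10⁻³ events/patient-day, true HR 0.5, two binary
confounders plus age).

**What the simulators do not emulate** — and hence what green tests do not
establish about real data: real MedDRA/ICD ontologies (term lists and code
prefixes stand in), correlated co-prescription beyond independent draws
plus polypharmacy, reporting biases and stimulated-reporting waves,
time-varying hazards or competing risks (censoring comes only from
disenrollment and the analysis horizon), dose/duration effects, and
measurement error in diagnosis coding. Passing recovery tests show the
*pipeline arithmetic* is right under the stated generative model, not that
any real-world association is causal.

## 7. Numerical choices and degenerate inputs

* CI critical values use `qnorm(0.975)` (= 1.959964); tests compare against
  1.96-based arithmetic at a correspondingly loose tolerance.
* Uncorrected zero-cell tables, in-class concomitants, single-arm matching
  inputs, empty groups in incidence or log-rank, and event-free groups in
  Cox all raise explicit errors; nothing silently returns infinities.
* Propensity fits that push fitted probabilities to the (0,1) boundary
  (perfect separation) are rejected with advice to reduce covariates.
* Matching ties in score distance are resolved toward the lower-score
  comparator (left neighbor) deterministically; the greedy order is the
  only seeded randomness in the analysis layer.
* Generators restore the caller's RNG state, so simulation is a pure
  function of `(config, seed)` and never perturbs the session stream.

## 8. Known limitations

Only pairwise interactions are screened (no three-drug terms, no shrinkage
or regression-based interaction models); matching is greedy rather than
optimal; there are no time-varying covariates, stratified Cox or
proportional-hazards diagnostics; FAERS/JADER quarterly-file parsing is out
of scope (the delimited-text schema is the interface, with a thin adapter
left to the user); and the enrichment step requires significance in every
database, which is conservative when databases differ greatly in size.
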