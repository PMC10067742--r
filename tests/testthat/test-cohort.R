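fq_spec <- function(...) {
  cohort_spec(outcome_codes = "M76", exposure_codes = "J01MA",
              comod_codes = "H02AB02", run_in_days = 180,
              window_before = 7, window_after = 30,
              risk_period_days = 30, follow_up_days = 60, ...)
}

test_that("run-in exclusion removes prevalent cases, prior users and short enrollments", {
  cs <- make_claims(list(
    list(id = "early_dx", start = 0, end = 400, dx = list(c(10, "M76.1"))),
    list(id = "clean", start = 0, end = 400,
         rx = list(c(200, "J01MA02", "oral"))),
    list(id = "early_rx", start = 0, end = 400,
         rx = list(c(50, "J01MA02", "oral"))),
    list(id = "early_comod", start = 0, end = 400,
         rx = list(c(50, "H02AB02", "topical"))),  # any route counts in run-in
    list(id = "short", start = 0, end = 100)
  ))
  elig <- apply_run_in(cs, fq_spec())
  expect_setequal(elig, "clean")
})

test_that("index assignment honors the concomitant window boundaries and the systemic-only rule", {
  spec <- fq_spec()
  cs <- make_claims(list(
    # dexamethasone 5 days before the FQ: inside the -7 bound
    list(id = "in_before", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(295, "H02AB02", "oral"))),
    # exactly at the -7 and +30 bounds: inclusive
    list(id = "at_minus7", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(293, "H02AB02", "oral"))),
    list(id = "at_plus30", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(330, "H02AB02", "oral"))),
    # 31 days after: outside, comparator
    list(id = "at_plus31", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(331, "H02AB02", "oral"))),
    # topical dexamethasone never qualifies as concomitant
    list(id = "topical_comod", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(300, "H02AB02", "topical"))),
    # only topical FQ: never indexed
    list(id = "topical_fq", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "topical"))),
    # index is the first systemic FQ at/after run-in end
    list(id = "two_fq", start = 0, end = 500,
         rx = list(c(250, "J01MA02", "oral"), c(400, "J01MA01", "oral")))
  ))
  elig <- apply_run_in(cs, spec)
  im <- assign_index(cs, spec, elig, design = "exposure")
  grp <- setNames(im$group, im$patient_id)
  expect_equal(unname(grp[c("in_before", "at_minus7", "at_plus30")]),
               rep("exposed", 3))
  expect_equal(unname(grp[c("at_plus31", "topical_comod")]),
               rep("comparator", 2))
  expect_false("topical_fq" %in% im$patient_id)
  expect_equal(im$index_day[im$patient_id == "two_fq"], 250)
})

test_that("survival records follow the min(outcome, disenrollment, horizon) rule", {
  spec <- fq_spec()
  cs <- make_claims(list(
    # no outcome, enrollment beyond follow-up: censored at the horizon
    list(id = "censored", start = 0, end = 500,
         rx = list(c(200, "J01MA02", "oral"))),
    # outcome at index + 10
    list(id = "event10", start = 0, end = 500,
         rx = list(c(200, "J01MA02", "oral")), dx = list(c(210, "M76"))),
    # disenrollment before the horizon
    list(id = "dropout", start = 0, end = 230,
         rx = list(c(200, "J01MA02", "oral"))),
    # outcome on the index day itself: time 0, event 1, kept
    list(id = "event0", start = 0, end = 500,
         rx = list(c(200, "J01MA02", "oral")), dx = list(c(200, "M76"))),
    # outcome after the horizon: censored at 60
    list(id = "late_event", start = 0, end = 500,
         rx = list(c(200, "J01MA02", "oral")), dx = list(c(290, "M76")))
  ))
  elig <- apply_run_in(cs, spec)
  im <- assign_index(cs, spec, elig, design = "exposure")
  recs <- build_survival(cs, spec, im)
  row <- function(id) recs[recs$patient_id == id, ]
  expect_equal(row("censored")[, c("time", "event")],
               data.frame(time = 60, event = 0L), ignore_attr = TRUE)
  expect_equal(row("event10")[, c("time", "event")],
               data.frame(time = 10, event = 1L), ignore_attr = TRUE)
  expect_equal(row("dropout")[, c("time", "event")],
               data.frame(time = 30, event = 0L), ignore_attr = TRUE)
  expect_equal(row("event0")[, c("time", "event")],
               data.frame(time = 0, event = 1L), ignore_attr = TRUE)
  expect_equal(row("late_event")[, c("time", "event")],
               data.frame(time = 60, event = 0L), ignore_attr = TRUE)
  expect_true(all(recs$time >= 0 & recs$time <= spec$follow_up_days))
})

test_that("covariate flags use the strictly pre-index half-open lookback window", {
  cs <- make_claims(list(
    list(id = "p1", start = 0, end = 500,
         rx = list(c(300, "J01MA02", "oral"), c(250, "WARF", "oral")),
         dx = list(c(300, "E11"),    # on index day: not counted
                   c(150, "N18"),    # within 180-day lookback
                   c(119, "I10")))   # day 119 < 300 - 180: outside
  ))
  im <- data.frame(patient_id = "p1", index_day = 300, group = "exposed",
                   stringsAsFactors = FALSE)
  cov <- build_covariates(cs, im, lookback_days = 180,
                          comorbidity_codes = list(diabetes = "E11",
                                                   ckd = "N18",
                                                   hypertension = "I10"),
                          medication_codes = list(warfarin = "WARF"))
  expect_equal(cov$diabetes, 0L)
  expect_equal(cov$ckd, 1L)
  expect_equal(cov$hypertension, 0L)
  expect_equal(cov$warfarin, 1L)
  # empty history gives all-zero flags
  cs2 <- make_claims(list(list(id = "p2", start = 0, end = 500)))
  cov2 <- build_covariates(cs2, data.frame(patient_id = "p2", index_day = 300,
                                           group = "comparator"),
                           comorbidity_codes = list(diabetes = "E11"))
  expect_equal(cov2$diabetes, 0L)
})

test_that("the older-adult design splits by concomitant use with the comparator clock at run-in end", {
  spec <- cohort_spec(outcome_codes = "M76", exposure_codes = "H02AB02",
                      comod_codes = "H02AB02", follow_up_days = 180,
                      min_age = 65)
  cs <- make_claims(list(
    list(id = "old_dex", age = 70, start = 0, end = 600,
         rx = list(c(300, "H02AB02", "oral"))),
    list(id = "old_none", age = 80, start = 0, end = 600),
    list(id = "young", age = 50, start = 0, end = 600)
  ))
  elig <- apply_run_in(cs, spec)
  im <- assign_index(cs, spec, elig, design = "age")
  expect_false("young" %in% im$patient_id)
  expect_equal(im$index_day[im$patient_id == "old_dex"], 300)
  expect_equal(im$group[im$patient_id == "old_dex"], "exposed")
  expect_equal(im$index_day[im$patient_id == "old_none"], 180)
  expect_equal(im$group[im$patient_id == "old_none"], "comparator")
})

test_that("cumulative incidence matches a hand tally with exact Clopper-Pearson CI", {
  recs <- data.frame(
    group = rep(c("exposed", "comparator"), c(100, 10)),
    event = c(rep(1, 2), rep(0, 98), rep(0, 10)))
  ci <- cumulative_incidence(recs)
  ex <- ci[ci$group == "exposed", ]
  expect_equal(ex$percent, 2)
  expect_equal(unlist(ex[, c("ci_low", "ci_high")]),
               unlist(binom.test(2, 100)$conf.int[1:2]), ignore_attr = TRUE)
  zero <- ci[ci$group == "comparator", ]
  expect_equal(zero$proportion, 0)
  expect_equal(zero$ci_low, 0)
  expect_error(cumulative_incidence(recs[0, ]), "empty")
})

test_that("the full cohort build matches a straight-line brute-force reimplementation", {
  cfg <- claims_sim_config(
    200, baseline_hazard = 3e-3, exposure_intercept = 0.5,
    route_topical_fraction = 0.25,
    anchor_codes = c("J01MA02", "J01MA12"), anchor_prob = 0.7,
    comod_window_prob = 0.5, seed = 99)
  cs <- simulate_claims(cfg)$claims
  spec <- fq_spec()
  elig <- apply_run_in(cs, spec)
  im <- assign_index(cs, spec, elig, design = "exposure")
  recs <- build_survival(cs, spec, im)
  got <- merge(im, recs[, c("patient_id", "time", "event")], by = "patient_id")
  got <- got[order(got$patient_id), ]
  want <- brute_force_cohort(cs, spec)
  want <- want[order(want$patient_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got[, c("patient_id", "index_day", "group", "time", "event")],
               want, ignore_attr = TRUE)
})
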