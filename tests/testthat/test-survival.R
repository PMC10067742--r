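test_that("KM with no events is flat at 1; without censoring it equals the empirical survival function", {
  recs <- data.frame(time = c(5, 10, 15, 20), event = 0,
                     group = "exposed")
  km <- km_estimate(recs, follow_up_days = 20)
  expect_true(all(km$curves$surv == 1))

  # 5 uncensored subjects, distinct event times
  times <- c(2, 4, 6, 8, 10)
  recs2 <- data.frame(time = times, event = 1, group = "exposed")
  km2 <- km_estimate(recs2, follow_up_days = 10)
  expect_equal(km2$curves$surv, 1 - seq_along(times) / 5)
})

test_that("KM on a hand-computed mixed fixture is exact to full precision", {
  # events at 1 (n=4), censor at 2, event at 3 (n=2), event at 4 (n=1):
  # S = 3/4, then 3/4 * 1/2 = 3/8, then 0
  recs <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1),
                     group = "g")
  km <- km_estimate(recs, follow_up_days = 4)
  ev <- km$curves[km$curves$n_event > 0, ]
  expect_equal(ev$surv, c(3 / 4, 3 / 8, 0))
  expect_equal(ev$cum_incidence, c(1 / 4, 5 / 8, 1))

  # 8-record two-group fixture against hand product-limit arithmetic
  recs8 <- data.frame(
    time = c(1, 3, 3, 7, 2, 2, 5, 6),
    event = c(1, 1, 0, 1, 1, 0, 1, 0),
    group = rep(c("exposed", "comparator"), each = 4))
  km8 <- km_estimate(recs8, follow_up_days = 7)
  ce <- km8$curves[km8$curves$group == "exposed" & km8$curves$n_event > 0, ]
  # exposed: event at 1 (4 at risk) -> 3/4; event at 3 (3 at risk, censor
  # leaves after the event) -> 3/4 * 2/3 = 1/2; event at 7 (1 at risk) -> 0
  expect_equal(ce$surv, c(3 / 4, 1 / 2, 0))
  cc <- km8$curves[km8$curves$group == "comparator" & km8$curves$n_event > 0, ]
  # comparator: event at 2 (4 at risk) -> 3/4; event at 5 (2 at risk) -> 3/8
  expect_equal(cc$surv, c(3 / 4, 3 / 8))
})

test_that("KM invariants: S(0) = 1, S non-increasing, survival + cumulative incidence = 1, risk counts non-increasing", {
  set.seed(71)
  recs <- data.frame(time = pmin(rexp(200, 0.05), 60),
                     event = rbinom(200, 1, 0.7),
                     group = sample(c("exposed", "comparator"), 200, TRUE))
  recs$event[recs$time >= 60] <- 0
  km <- km_estimate(recs, follow_up_days = 60)
  for (g in unique(recs$group)) {
    cur <- km$curves[km$curves$group == g, ]
    expect_true(all(diff(cur$surv) <= 1e-12))
    expect_equal(cur$surv + cur$cum_incidence, rep(1, nrow(cur)))
    ar <- km$at_risk[km$at_risk$group == g, ]
    expect_equal(ar$n_risk[1], sum(recs$group == g))  # S(0): everyone at risk
    expect_true(all(diff(ar$n_risk) <= 0))
  }
})

test_that("daily number at risk counts subjects still under observation and event-free", {
  recs <- data.frame(time = c(0, 2, 5, 5), event = c(1, 0, 1, 0), group = "g")
  km <- km_estimate(recs, follow_up_days = 6)
  ar <- km$at_risk
  expect_equal(ar$n_risk[ar$day == 0], 4)
  expect_equal(ar$n_risk[ar$day == 1], 3)
  expect_equal(ar$n_risk[ar$day == 3], 2)
  expect_equal(ar$n_risk[ar$day == 5], 2)
  expect_equal(ar$n_risk[ar$day == 6], 0)
})

test_that("log-rank statistic matches a hand O-E / V computation and is zero for identical groups", {
  recs <- data.frame(
    time = c(1, 2, 4, 6, 8, 1, 3, 5, 7, 9),
    event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0),
    group = rep(c("a", "b"), each = 5))
  # independent hypergeometric O-E/V accumulation over distinct event times
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(recs$time[recs$event == 1]))) {
    at_risk <- recs$time >= t
    d <- sum(recs$event == 1 & recs$time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & recs$group == "a")
    d1 <- sum(recs$event == 1 & recs$time == t & recs$group == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expected_chisq <- o_minus_e^2 / v
  lr <- log_rank(recs)
  expect_equal(lr$chisq, expected_chisq)
  expect_equal(lr$p, pchisq(expected_chisq, 1, lower.tail = FALSE))

  # identical (time, event) multisets in both groups
  same <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                     event = rep(c(1, 1, 0, 1), 2),
                     group = rep(c("a", "b"), each = 4))
  expect_lt(log_rank(same)$chisq, 1e-12)
  expect_error(log_rank(same[same$group == "a", ]), "two")
})

test_that("log-rank type-I error is near 5% under the null", {
  set.seed(72)
  n_rej <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    recs <- data.frame(time = rexp(400, 0.1), event = 1,
                       group = rep(c("a", "b"), each = 200))
    cens <- recs$time > 15
    recs$event[cens] <- 0
    recs$time[cens] <- 15
    if (log_rank(recs)$p < 0.05) n_rej <- n_rej + 1
  }
  rate <- n_rej / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Cox score equation root on a tie-free fixture matches a bisection solution", {
  # subjects (time, event, exposed): two distinct events, no ties
  recs <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                     group = c("exposed", "comparator", "exposed", "comparator"))
  x <- c(1, 0, 1, 0)
  # partial-likelihood score: at t=1 risk {1,2,3,4}, at t=2 risk {2,3,4}
  score <- function(b) {
    (1 - (2 * exp(b)) / (2 * exp(b) + 2)) + (0 - exp(b) / (exp(b) + 2))
  }
  root <- uniroot(score, c(-10, 10), tol = 1e-12)$root
  cx <- cox_hr(recs)
  expect_equal(cx$log_hr, root, tolerance = 1e-6)
  expect_equal(cx$hr, exp(root), tolerance = 1e-6)
  expect_true(cx$ci_low <= cx$hr && cx$hr <= cx$ci_high)
})

test_that("two-group log-rank equals the Cox score test at beta = 0 on tie-free data", {
  set.seed(73)
  recs <- data.frame(time = rexp(120, 0.1) + runif(120) * 1e-6, event = rbinom(120, 1, 0.8),
                     group = rep(c("exposed", "comparator"), each = 60))
  expect_equal(anyDuplicated(recs$time), 0)
  lr <- log_rank(recs)
  cx <- cox_hr(recs, ties = "breslow")
  sc <- summary(cx$fit)$sctest[["test"]]
  expect_equal(lr$chisq, sc, tolerance = 1e-8)
})

test_that("Cox under a permuted-label null estimates an HR within 3 SEs of 1", {
  set.seed(74)
  n <- 2000
  recs <- data.frame(time = rexp(2 * n, 0.05), event = 1,
                     group = sample(rep(c("exposed", "comparator"), n)))
  cens <- recs$time > 30
  recs$event[cens] <- 0; recs$time[cens] <- 30
  cx <- cox_hr(recs)
  expect_lt(abs(cx$log_hr) / cx$se, 3)
  expect_true(cx$ci_low <= cx$hr && cx$hr <= cx$ci_high)
})

test_that("a group without events raises an informative error", {
  recs <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                     group = rep(c("exposed", "comparator"), c(2, 2)))
  expect_error(cox_hr(recs), "at least one event")
})
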