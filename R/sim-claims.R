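#' Configuration for the synthetic claims simulator
#'
#' Defines a patient-level generative model for longitudinal claims with
#' known ground truth: enrollment churn, binary and age confounders that
#' shift both the probability of receiving the exposure drug and the event
#' hazard, systemic/topical prescription routes, an optional anchor drug
#' (e.g. a fluoroquinolone around which the exposure may be co-prescribed),
#' and an outcome event stream.
#'
#' The outcome is generated as a homogeneous Poisson process over the
#' enrollment span with per-patient rate
#' `baseline_hazard * exp(sum(covariate effects) + exposure_log_hr * exposed)`.
#' Using a full event stream (rather than a single latent time) makes the
#' first event after *any* index day exactly exponential with the same rate,
#' so run-in exclusion and index-date conventions downstream introduce no
#' selection bias into hazard-ratio recovery.
#'
#' @param n_patients number of patients.
#' @param enrollment_window integer `c(start, end)` day offsets bounding all
#'   enrollment spans.
#' @param mean_enrollment_days mean span length (exponential lengths,
#'   truncated to the window; minimum 30 days).
#' @param age_distribution `c(mean, sd)` in years.
#' @param covariate_spec data.frame with columns `name`, `prevalence`,
#'   `exposure_log_odds`, `log_hr`: binary comorbidity-style confounders.
#'   Each is materialized as a diagnosis record with code `"COV_<name>"`
#'   early in enrollment so the covariate builder can recover it. May be
#'   `NULL`.
#' @param age_exposure_log_odds,age_log_hr confounding through age, per SD
#'   of the age distribution.
#' @param exposure_codes drug code(s) written on exposure prescriptions
#'   (e.g. `"H02AB02"`).
#' @param exposure_intercept intercept of the logistic exposure model.
#' @param route_topical_fraction fraction of prescriptions with route
#'   `"topical"` (the rest are `"oral"`), in [0,1].
#' @param baseline_hazard outcome events per patient-day, >= 0.
#' @param exposure_log_hr log hazard ratio of the exposure.
#' @param anchor_codes optional drug code(s) for an anchor prescription
#'   given to a `anchor_prob` fraction of patients at a uniform day; when
#'   present, an exposed patient's exposure prescription is placed inside
#'   `anchor_window` around the anchor day with probability
#'   `comod_window_prob` (uniform in enrollment otherwise).
#' @param anchor_prob,comod_window_prob,anchor_window see `anchor_codes`.
#' @param outcome_code diagnosis code written on outcome records.
#' @param seed integer seed; generation is a pure function of
#'   (config, seed).
#' @return object of class `claims_sim_config`.
#' @export
claims_sim_config <- function(n_patients,
                              enrollment_window = c(0L, 1095L),
                              mean_enrollment_days = 720,
                              age_distribution = c(55, 12),
                              covariate_spec = NULL,
                              age_exposure_log_odds = 0,
                              age_log_hr = 0,
                              exposure_codes = "H02AB02",
                              exposure_intercept = -1,
                              route_topical_fraction = 0,
                              baseline_hazard = 1e-4,
                              exposure_log_hr = 0,
                              anchor_codes = NULL,
                              anchor_prob = 0,
                              comod_window_prob = 0.5,
                              anchor_window = c(-7L, 30L),
                              outcome_code = "M76",
                              seed = 1L) {
  if (baseline_hazard < 0) {
    stop("invalid 'baseline_hazard': must be >= 0", call. = FALSE)
  }
  if (route_topical_fraction < 0 || route_topical_fraction > 1) {
    stop("invalid 'route_topical_fraction': must lie in [0,1]", call. = FALSE)
  }
  if (anchor_prob < 0 || anchor_prob > 1) {
    stop("invalid 'anchor_prob': must lie in [0,1]", call. = FALSE)
  }
  stopifnot(length(enrollment_window) == 2L,
            enrollment_window[2] > enrollment_window[1],
            length(age_distribution) == 2L, age_distribution[2] > 0)
  if (!is.null(covariate_spec)) {
    stopifnot(is.data.frame(covariate_spec),
              all(c("name", "prevalence", "exposure_log_odds", "log_hr") %in%
                    names(covariate_spec)))
    if (any(covariate_spec$prevalence <= 0 | covariate_spec$prevalence >= 1)) {
      stop("invalid 'covariate_spec': prevalences must lie in (0,1)",
           call. = FALSE)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 enrollment_window = as.integer(enrollment_window),
                 mean_enrollment_days = mean_enrollment_days,
                 age_distribution = age_distribution,
                 covariate_spec = covariate_spec,
                 age_exposure_log_odds = age_exposure_log_odds,
                 age_log_hr = age_log_hr,
                 exposure_codes = exposure_codes,
                 exposure_intercept = exposure_intercept,
                 route_topical_fraction = route_topical_fraction,
                 baseline_hazard = baseline_hazard,
                 exposure_log_hr = exposure_log_hr,
                 anchor_codes = anchor_codes,
                 anchor_prob = anchor_prob,
                 comod_window_prob = comod_window_prob,
                 anchor_window = as.integer(anchor_window),
                 outcome_code = outcome_code,
                 seed = as.integer(seed)),
            class = "claims_sim_config")
}

#' Simulate longitudinal claims with known ground truth
#'
#' @param config a [claims_sim_config()].
#' @return list with `claims` (a [claims_store]) and `truth` (list:
#'   `exposure_log_hr`, `hr`, `covariate_spec`, per-patient `exposed` flag,
#'   covariate matrix and event rate).
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "claims_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_patients
  w <- config$enrollment_window
  width <- w[2] - w[1]

  s <- w[1] + sample.int(max(1L, floor(width * 0.1)), n, replace = TRUE) - 1L
  len <- pmax(30L, as.integer(round(stats::rexp(n, 1 / config$mean_enrollment_days))))
  e <- pmax(pmin(s + len, w[2]), s + 1L)
  age <- round(stats::rnorm(n, config$age_distribution[1], config$age_distribution[2]))
  z_age <- (age - config$age_distribution[1]) / config$age_distribution[2]
  sex <- sample(c("F", "M"), n, replace = TRUE)
  pid <- sprintf("P%06d", seq_len(n))

  cov_names <- character(0)
  X <- NULL
  if (!is.null(config$covariate_spec) && nrow(config$covariate_spec) > 0L) {
    cov_names <- config$covariate_spec$name
    X <- vapply(config$covariate_spec$prevalence,
                function(p) stats::runif(n) < p, logical(n))
    colnames(X) <- cov_names
  }

  # confounded exposure assignment
  eta <- rep(config$exposure_intercept, n) + config$age_exposure_log_odds * z_age
  if (!is.null(X)) {
    eta <- eta + as.vector(X %*% config$covariate_spec$exposure_log_odds)
  }
  # anchor drug (optional): exposure can only be co-prescribed around it
  has_anchor <- rep(FALSE, n)
  anchor_day <- rep(NA_integer_, n)
  if (!is.null(config$anchor_codes) && config$anchor_prob > 0) {
    has_anchor <- stats::runif(n) < config$anchor_prob
    anchor_day <- ifelse(has_anchor,
                         s + floor(stats::runif(n) * (e - s)), NA_integer_)
  }
  exposed <- stats::runif(n) < stats::plogis(eta)
  if (!is.null(config$anchor_codes)) exposed <- exposed & has_anchor

  # exposure prescription day
  exp_day <- rep(NA_integer_, n)
  in_window <- stats::runif(n) < config$comod_window_prob
  for_exp <- which(exposed)
  if (length(for_exp) > 0L) {
    lo <- s[for_exp]
    hi <- e[for_exp] - 1L
    use_win <- !is.na(anchor_day[for_exp]) & in_window[for_exp]
    wlo <- pmax(lo, anchor_day[for_exp] + config$anchor_window[1])
    whi <- pmin(hi, anchor_day[for_exp] + config$anchor_window[2])
    use_win <- use_win & wlo <= whi
    lo[use_win] <- wlo[use_win]
    hi[use_win] <- whi[use_win]
    exp_day[for_exp] <- lo + floor(stats::runif(length(for_exp)) * (hi - lo + 1L))
  }

  # outcome event stream: homogeneous Poisson process over enrollment
  log_rate <- log(config$baseline_hazard) + config$age_log_hr * z_age +
    config$exposure_log_hr * as.numeric(exposed)
  if (!is.null(X)) {
    log_rate <- log_rate + as.vector(X %*% config$covariate_spec$log_hr)
  }
  rate <- if (config$baseline_hazard == 0) rep(0, n) else exp(log_rate)
  n_events <- stats::rpois(n, rate * (e - s))
  ev_pid <- rep(pid, n_events)
  ev_s <- rep(s, n_events)
  ev_len <- rep(e - s, n_events)
  ev_day <- ev_s + floor(stats::runif(length(ev_pid)) * ev_len)

  # assemble tables
  patients <- data.frame(patient_id = pid, age = age, sex = sex,
                         enroll_start = s, enroll_end = e,
                         stringsAsFactors = FALSE)

  rx <- list()
  if (any(has_anchor)) {
    ia <- which(has_anchor)
    rx[["anchor"]] <- data.frame(
      patient_id = pid[ia], day = anchor_day[ia],
      code = sample(rep_len(config$anchor_codes, length(ia))),
      route = ifelse(stats::runif(length(ia)) < config$route_topical_fraction,
                     "topical", "oral"),
      days_supplied = 7L, stringsAsFactors = FALSE)
  }
  if (length(for_exp) > 0L) {
    rx[["exposure"]] <- data.frame(
      patient_id = pid[for_exp], day = exp_day[for_exp],
      code = sample(rep_len(config$exposure_codes, length(for_exp))),
      route = ifelse(stats::runif(length(for_exp)) < config$route_topical_fraction,
                     "topical", "oral"),
      days_supplied = 5L, stringsAsFactors = FALSE)
  }
  prescriptions <- if (length(rx) > 0L) do.call(rbind, rx) else
    data.frame(patient_id = character(0), day = integer(0),
               code = character(0), route = character(0),
               days_supplied = integer(0), stringsAsFactors = FALSE)
  rownames(prescriptions) <- NULL

  dx <- list()
  if (length(ev_day) > 0L) {
    dx[["outcome"]] <- data.frame(patient_id = ev_pid, day = ev_day,
                                  code = config$outcome_code,
                                  stringsAsFactors = FALSE)
  }
  if (!is.null(X)) {
    for (j in seq_along(cov_names)) {
      ij <- which(X[, j])
      if (length(ij) == 0L) next
      # chronic condition recorded once, early in enrollment (pre-index for
      # any index at or after the run-in end)
      hi <- pmin(s[ij] + 179L, e[ij] - 1L)
      dx[[cov_names[j]]] <- data.frame(
        patient_id = pid[ij],
        day = s[ij] + floor(stats::runif(length(ij)) * (hi - s[ij] + 1L)),
        code = paste0("COV_", cov_names[j]), stringsAsFactors = FALSE)
    }
  }
  diagnoses <- if (length(dx) > 0L) do.call(rbind, dx) else
    data.frame(patient_id = character(0), day = integer(0),
               code = character(0), stringsAsFactors = FALSE)
  rownames(diagnoses) <- NULL

  truth <- list(exposure_log_hr = config$exposure_log_hr,
                hr = exp(config$exposure_log_hr),
                covariate_spec = config$covariate_spec,
                age_log_hr = config$age_log_hr,
                exposed = stats::setNames(exposed, pid),
                covariates = X,
                rate = stats::setNames(rate, pid))
  list(claims = claims_store(patients, prescriptions, diagnoses),
       truth = truth)
}
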