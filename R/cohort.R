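#' Cohort specification for the claims pipeline
#'
#' Collects the code lists and time windows that define a new-user cohort:
#' a run-in period excluding prevalent cases and prior users, systemic-route
#' exposure and concomitant code lists, the concomitant-use window around
#' the index prescription, and the follow-up horizon.
#'
#' Defaults mirror a design in which patients with an outcome diagnosis or
#' an exposure/concomitant prescription during the first 6 months of
#' enrollment are excluded (`run_in_days = 180`), concomitant use means a
#' prescription from 7 days before to 30 days after the index prescription
#' (`window_before = 7`, `window_after = 30`, both boundaries inclusive),
#' the outcome risk period is 30 days, and follow-up runs for twice the risk
#' period (60 days; 180 for the older-adult design).
#'
#' @param outcome_codes diagnosis code prefixes defining the outcome.
#' @param exposure_codes drug codes of the index exposure (e.g. a
#'   fluoroquinolone ATC list).
#' @param comod_codes drug codes of the concomitant drug (e.g.
#'   dexamethasone).
#' @param run_in_days run-in length in days.
#' @param window_before,window_after concomitant-use window bounds, days.
#' @param risk_period_days outcome risk period, days.
#' @param follow_up_days follow-up horizon, days; must be >=
#'   `risk_period_days`.
#' @param min_age optional minimum age (65 for the older-adult design).
#' @param systemic_only when `TRUE` (default) prescriptions whose route is
#'   in `topical_routes` never qualify for index or concomitant status.
#' @param topical_routes routes treated as topical.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(outcome_codes,
                        exposure_codes,
                        comod_codes,
                        run_in_days = 180L,
                        window_before = 7L,
                        window_after = 30L,
                        risk_period_days = 30L,
                        follow_up_days = 60L,
                        min_age = NULL,
                        systemic_only = TRUE,
                        topical_routes = "topical") {
  durations <- c(run_in_days, window_before, window_after,
                 risk_period_days, follow_up_days)
  if (any(durations < 0)) stop("all durations must be >= 0", call. = FALSE)
  if (follow_up_days < risk_period_days) {
    stop("follow_up_days must be >= risk_period_days", call. = FALSE)
  }
  structure(list(outcome_codes = outcome_codes,
                 exposure_codes = exposure_codes,
                 comod_codes = comod_codes,
                 run_in_days = as.integer(run_in_days),
                 window_before = as.integer(window_before),
                 window_after = as.integer(window_after),
                 risk_period_days = as.integer(risk_period_days),
                 follow_up_days = as.integer(follow_up_days),
                 min_age = min_age,
                 systemic_only = systemic_only,
                 topical_routes = topical_routes),
            class = "cohort_spec")
}

code_match <- function(codes, code_list) {
  # prefix match so "M76" covers "M76.0" style subcodes
  if (length(code_list) == 0L) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (cl in code_list) out <- out | startsWith(codes, cl)
  out
}

systemic <- function(rx, spec) {
  if (!spec$systemic_only) rep(TRUE, nrow(rx))
  else !(rx$route %in% spec$topical_routes)
}

#' Apply the run-in exclusion
#'
#' Excludes patients whose enrollment is shorter than `run_in_days` and
#' patients with an outcome diagnosis, an exposure prescription or a
#' concomitant-drug prescription (any route) during
#' `[enroll_start, enroll_start + run_in_days)`. This removes prevalent
#' cases and prior users so downstream events are incident and exposures
#' new.
#'
#' @param cs a [claims_store].
#' @param spec a [cohort_spec()].
#' @return character vector of eligible patient ids.
#' @export
apply_run_in <- function(cs, spec) {
  stopifnot(inherits(cs, "claims_store"), inherits(spec, "cohort_spec"))
  p <- cs$patients
  eligible <- p$enroll_end - p$enroll_start >= spec$run_in_days
  run_in_end <- p$enroll_start + spec$run_in_days

  dx <- cs$diagnoses
  if (nrow(dx) > 0L) {
    i <- match(dx$patient_id, p$patient_id)
    bad_dx <- code_match(dx$code, spec$outcome_codes) &
      dx$day >= p$enroll_start[i] & dx$day < run_in_end[i]
    eligible[match(unique(dx$patient_id[bad_dx]), p$patient_id)] <- FALSE
  }
  rx <- cs$prescriptions
  if (nrow(rx) > 0L) {
    i <- match(rx$patient_id, p$patient_id)
    bad_rx <- (code_match(rx$code, spec$exposure_codes) |
                 code_match(rx$code, spec$comod_codes)) &
      rx$day >= p$enroll_start[i] & rx$day < run_in_end[i]
    eligible[match(unique(rx$patient_id[bad_rx]), p$patient_id)] <- FALSE
  }
  p$patient_id[eligible]
}

#' Assign index dates and exposure groups
#'
#' Two designs are supported.
#'
#' `"exposure"` (new-user active drug design): the index date is the day of
#' the first systemic exposure-code prescription at or after the end of the
#' run-in; the patient is in the concomitant group if a systemic
#' concomitant-code prescription falls in
#' `[index - window_before, index + window_after]` (boundaries inclusive),
#' and in the comparator group otherwise. Patients with only topical
#' exposure prescriptions are never indexed when `systemic_only`.
#'
#' `"age"` (older-adult design): patients with `age >= min_age` are split by
#' concomitant-drug use; the concomitant group's index is the day of the
#' first systemic concomitant-code prescription at or after the end of the
#' run-in, the comparator group's clock starts at the end of the run-in
#' (patients with no systemic concomitant prescription at all).
#'
#' @param cs a [claims_store].
#' @param spec a [cohort_spec()].
#' @param eligible patient ids from [apply_run_in()].
#' @param design `"exposure"` or `"age"`.
#' @return data.frame `index_map` with columns `patient_id`, `index_day`,
#'   `group` (`"exposed"` = with concomitant drug, `"comparator"`).
#' @export
assign_index <- function(cs, spec, eligible, design = c("exposure", "age")) {
  stopifnot(inherits(cs, "claims_store"), inherits(spec, "cohort_spec"))
  design <- match.arg(design)
  p <- cs$patients[cs$patients$patient_id %in% eligible, , drop = FALSE]
  rx <- cs$prescriptions[cs$prescriptions$patient_id %in% eligible, , drop = FALSE]
  run_in_end <- stats::setNames(p$enroll_start + spec$run_in_days, p$patient_id)
  sys <- systemic(rx, spec)

  first_day_after <- function(codes) {
    sel <- code_match(rx$code, codes) & sys &
      rx$day >= run_in_end[rx$patient_id]
    if (!any(sel)) return(integer(0))
    tapply(rx$day[sel], rx$patient_id[sel], min)
  }

  if (design == "exposure") {
    idx <- first_day_after(spec$exposure_codes)
    if (length(idx) == 0L) {
      return(data.frame(patient_id = character(0), index_day = integer(0),
                        group = character(0), stringsAsFactors = FALSE))
    }
    ids <- names(idx)
    index_day <- as.integer(idx)
    comod_sel <- code_match(rx$code, spec$comod_codes) & sys
    comod <- rx[comod_sel, , drop = FALSE]
    idx_of <- stats::setNames(index_day, ids)
    in_window <- comod$patient_id %in% ids &
      comod$day >= idx_of[comod$patient_id] - spec$window_before &
      comod$day <= idx_of[comod$patient_id] + spec$window_after
    exposed_ids <- unique(comod$patient_id[in_window])
    out <- data.frame(patient_id = ids, index_day = index_day,
                      group = ifelse(ids %in% exposed_ids,
                                     "exposed", "comparator"),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(spec$min_age)) {
      stop("the age design requires 'min_age' in the cohort spec", call. = FALSE)
    }
    p <- p[p$age >= spec$min_age, , drop = FALSE]
    rx <- rx[rx$patient_id %in% p$patient_id, , drop = FALSE]
    sys <- systemic(rx, spec)
    idx <- first_day_after(spec$comod_codes)
    exposed_ids <- names(idx)
    any_comod <- unique(rx$patient_id[code_match(rx$code, spec$comod_codes) & sys])
    comp_ids <- setdiff(p$patient_id, any_comod)
    out <- rbind(
      data.frame(patient_id = exposed_ids,
                 index_day = as.integer(idx),
                 group = "exposed", stringsAsFactors = FALSE),
      data.frame(patient_id = comp_ids,
                 index_day = as.integer(run_in_end[comp_ids]),
                 group = "comparator", stringsAsFactors = FALSE)
    )
  }
  rownames(out) <- NULL
  out
}

#' Build survival records over the follow-up horizon
#'
#' For each indexed patient, follow-up ends at the first of: the first
#' outcome diagnosis at or after the index day, disenrollment, or
#' `index + follow_up_days`. `time` is that day minus the index day and
#' `event` is 1 iff the minimum is an outcome day. An outcome on the index
#' day itself gives `time = 0, event = 1` and is kept.
#'
#' @param cs a [claims_store].
#' @param spec a [cohort_spec()].
#' @param index_map data.frame from [assign_index()].
#' @return data.frame of class `survival_records`: `patient_id`, `group`,
#'   `index_day`, `time`, `event`.
#' @export
build_survival <- function(cs, spec, index_map) {
  stopifnot(inherits(cs, "claims_store"), inherits(spec, "cohort_spec"))
  p <- cs$patients
  i <- match(index_map$patient_id, p$patient_id)
  if (anyNA(i)) stop("index map references unknown patient ids", call. = FALSE)
  index_day <- index_map$index_day
  enroll_end <- p$enroll_end[i]

  dx <- cs$diagnoses[code_match(cs$diagnoses$code, spec$outcome_codes), ,
                     drop = FALSE]
  idx_of <- stats::setNames(index_day, index_map$patient_id)
  post <- dx[dx$patient_id %in% index_map$patient_id &
               dx$day >= idx_of[dx$patient_id], , drop = FALSE]
  first_out <- if (nrow(post) > 0L) {
    tapply(post$day, post$patient_id, min)
  } else {
    stats::setNames(integer(0), character(0))
  }
  out_day <- rep(Inf, nrow(index_map))
  hit <- match(names(first_out), index_map$patient_id)
  out_day[hit] <- as.numeric(first_out)

  end_day <- pmin(out_day, enroll_end, index_day + spec$follow_up_days)
  time <- end_day - index_day
  event <- as.integer(out_day == end_day)
  out <- data.frame(patient_id = index_map$patient_id,
                    group = index_map$group,
                    index_day = index_day,
                    time = as.numeric(time),
                    event = event,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_records", "data.frame")
  attr(out, "follow_up_days") <- spec$follow_up_days
  out
}

#' Assemble pre-index covariates
#'
#' Flags are computed strictly from records on days before the index day,
#' within `[index - lookback_days, index)`; a diagnosis on the index day
#' itself never counts. Age and sex come from the patients table.
#'
#' @param cs a [claims_store].
#' @param index_map data.frame from [assign_index()].
#' @param lookback_days history window length in days; `Inf` uses all
#'   pre-index history.
#' @param comorbidity_codes named list of diagnosis-code vectors, one flag
#'   column per entry.
#' @param medication_codes named list of drug-code vectors, one
#'   recent-medication flag column per entry.
#' @return data.frame: `patient_id`, `group`, `age`, `sex`, then one 0/1
#'   column per comorbidity and medication flag.
#' @export
build_covariates <- function(cs, index_map, lookback_days = 180,
                             comorbidity_codes = NULL,
                             medication_codes = NULL) {
  stopifnot(inherits(cs, "claims_store"))
  p <- cs$patients
  i <- match(index_map$patient_id, p$patient_id)
  if (anyNA(i)) stop("index map references unknown patient ids", call. = FALSE)
  out <- data.frame(patient_id = index_map$patient_id,
                    group = index_map$group,
                    age = p$age[i],
                    sex = p$sex[i],
                    stringsAsFactors = FALSE)
  idx_of <- stats::setNames(index_map$index_day, index_map$patient_id)

  flag_from <- function(df, codes) {
    sel <- df$patient_id %in% index_map$patient_id &
      code_match(df$code, codes) &
      df$day < idx_of[df$patient_id] &
      df$day >= idx_of[df$patient_id] - lookback_days
    as.integer(out$patient_id %in% unique(df$patient_id[sel]))
  }
  for (nm in names(comorbidity_codes)) {
    out[[nm]] <- flag_from(cs$diagnoses, comorbidity_codes[[nm]])
  }
  for (nm in names(medication_codes)) {
    out[[nm]] <- flag_from(cs$prescriptions, medication_codes[[nm]])
  }
  out
}

#' Cumulative incidence proportion per group
#'
#' Events over denominator per group, with an exact Clopper-Pearson 95%
#' confidence interval.
#'
#' @param records a `survival_records` data.frame (needs `group`, `event`).
#' @param conf_level confidence level.
#' @return data.frame: `group`, `n`, `events`, `proportion`, `percent`,
#'   `ci_low`, `ci_high` (proportion scale).
#' @export
cumulative_incidence <- function(records, conf_level = 0.95) {
  if (nrow(records) == 0L) stop("empty record table", call. = FALSE)
  groups <- sort(unique(records$group))
  rows <- lapply(groups, function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("empty group: ", g, call. = FALSE)
    x <- sum(sub$event)
    n <- nrow(sub)
    ci <- stats::binom.test(x, n, conf.level = conf_level)$conf.int
    data.frame(group = g, n = n, events = x, proportion = x / n,
               percent = 100 * x / n, ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
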