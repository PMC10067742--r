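# Shared fixture builders and independent oracles used across test files.

tendo_query <- function() event_query("tendinopathy", "tendinopathy")

# small handcrafted report set; drugs/events as ";"-separated strings
make_report_df <- function(report_id, case_id, version, drugs, events,
                           age = NA, sex = NA) {
  n <- length(report_id)
  data.frame(report_id = report_id, case_id = case_id,
             version = rep_len(version, n), drugs = rep_len(drugs, n),
             events = rep_len(events, n), age = rep_len(age, n),
             sex = rep_len(sex, n), stringsAsFactors = FALSE)
}

# independent direct-arithmetic ROR oracle (same published formulas, coded
# separately from the package path)
oracle_ror <- function(a, b, c, d, correct = TRUE) {
  if (correct) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  ror <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zc <- qnorm(0.975)
  list(ror = ror,
       ci_low = exp(log(ror) - zc * se),
       ci_high = exp(log(ror) + zc * se),
       z = log(ror) / se)
}

# brute-force double-loop contingency oracle over a report set
oracle_contingency <- function(rs, drug, terms) {
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(rs))) {
    exposed <- drug %in% rs$drugs[[i]]
    case <- any(tolower(trimws(rs$events[[i]])) %in% tolower(terms))
    if (exposed && case) a <- a + 1L
    else if (exposed) b <- b + 1L
    else if (case) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# random report set with arbitrary drug/event structure for property tests
random_report_set <- function(n, n_drugs = 6, seed = 1) {
  set.seed(seed)
  drugs <- paste0("drug", seq_len(n_drugs))
  df <- make_report_df(
    report_id = sprintf("R%05d", seq_len(n)),
    case_id = sprintf("C%05d", seq_len(n)),
    version = 1L,
    drugs = vapply(seq_len(n), function(i) {
      k <- rpois(1, 1.5)
      paste(sample(drugs, min(k, n_drugs)), collapse = ";")
    }, character(1)),
    events = ifelse(runif(n) < 0.3, "tendinopathy",
                    ifelse(runif(n) < 0.5, "nausea", ""))
  )
  report_set(df, provenance = paste0("DB", seed))
}

# small claims store built by hand: one list(...) per patient with optional
# rx = list(c(day, code, route)), dx = list(c(day, code))
make_claims <- function(patients) {
  p <- do.call(rbind, lapply(patients, function(x)
    data.frame(patient_id = x$id, age = x$age %||% 50, sex = x$sex %||% "F",
               enroll_start = x$start, enroll_end = x$end,
               stringsAsFactors = FALSE)))
  rx <- do.call(rbind, lapply(patients, function(x) {
    if (is.null(x$rx)) return(NULL)
    do.call(rbind, lapply(x$rx, function(r)
      data.frame(patient_id = x$id, day = as.integer(r[[1]]), code = r[[2]],
                 route = if (length(r) >= 3) r[[3]] else "oral",
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(rx)) rx <- data.frame(patient_id = character(0), day = integer(0),
                                    code = character(0), route = character(0))
  dx <- do.call(rbind, lapply(patients, function(x) {
    if (is.null(x$dx)) return(NULL)
    do.call(rbind, lapply(x$dx, function(r)
      data.frame(patient_id = x$id, day = as.integer(r[[1]]), code = r[[2]],
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(dx)) dx <- data.frame(patient_id = character(0), day = integer(0),
                                    code = character(0))
  claims_store(p, rx, dx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full older-adult-design pipeline on simulated claims: run-in -> index ->
# survival + covariates -> propensity match -> unmatched and matched Cox
run_older_pipeline <- function(cfg, caliper = 0.2, match_seed = 1) {
  sim <- simulate_claims(cfg)
  spec <- cohort_spec(outcome_codes = cfg$outcome_code,
                      exposure_codes = cfg$exposure_codes,
                      comod_codes = cfg$exposure_codes,
                      follow_up_days = 180, min_age = 0)
  elig <- apply_run_in(sim$claims, spec)
  im <- assign_index(sim$claims, spec, elig, design = "age")
  recs <- build_survival(sim$claims, spec, im)
  comorb <- NULL
  if (!is.null(cfg$covariate_spec)) {
    comorb <- lapply(cfg$covariate_spec$name, function(nm) paste0("COV_", nm))
    names(comorb) <- cfg$covariate_spec$name
  }
  cov <- build_covariates(sim$claims, im, lookback_days = Inf,
                          comorbidity_codes = comorb)
  pm <- fit_propensity(cov)
  mc <- match_cohort(pm, caliper = caliper, seed = match_seed)
  mrecs <- recs[recs$patient_id %in% matched_ids(mc), ]
  list(sim = sim, spec = spec, records = recs, covariates = cov,
       model = pm, matched = mc, matched_records = mrecs,
       cox_unmatched = cox_hr(recs), cox_matched = cox_hr(mrecs))
}

# straight-line per-patient reimplementation of the cohort build
# (run-in -> exposure-design index with concomitant window -> time/event),
# deliberately written as plain loops
brute_force_cohort <- function(cs, spec) {
  out <- NULL
  for (i in seq_len(nrow(cs$patients))) {
    p <- cs$patients[i, ]
    rx <- cs$prescriptions[cs$prescriptions$patient_id == p$patient_id, ]
    dx <- cs$diagnoses[cs$diagnoses$patient_id == p$patient_id, ]
    run_end <- p$enroll_start + spec$run_in_days
    if (p$enroll_end - p$enroll_start < spec$run_in_days) next
    is_out <- function(code) any(startsWith(code, spec$outcome_codes))
    is_exp <- function(code) any(startsWith(code, spec$exposure_codes))
    is_com <- function(code) any(startsWith(code, spec$comod_codes))
    bad <- FALSE
    for (j in seq_len(nrow(dx))) {
      if (is_out(dx$code[j]) && dx$day[j] >= p$enroll_start && dx$day[j] < run_end)
        bad <- TRUE
    }
    for (j in seq_len(nrow(rx))) {
      if ((is_exp(rx$code[j]) || is_com(rx$code[j])) &&
          rx$day[j] >= p$enroll_start && rx$day[j] < run_end)
        bad <- TRUE
    }
    if (bad) next
    # index: first systemic exposure prescription at/after run-in end
    index <- Inf
    for (j in seq_len(nrow(rx))) {
      if (is_exp(rx$code[j]) && !(rx$route[j] %in% spec$topical_routes) &&
          rx$day[j] >= run_end && rx$day[j] < index)
        index <- rx$day[j]
    }
    if (!is.finite(index)) next
    # concomitant flag: systemic comod rx in [index-before, index+after]
    exposed <- FALSE
    for (j in seq_len(nrow(rx))) {
      if (is_com(rx$code[j]) && !(rx$route[j] %in% spec$topical_routes) &&
          rx$day[j] >= index - spec$window_before &&
          rx$day[j] <= index + spec$window_after)
        exposed <- TRUE
    }
    # time/event
    first_out <- Inf
    for (j in seq_len(nrow(dx))) {
      if (is_out(dx$code[j]) && dx$day[j] >= index && dx$day[j] < first_out)
        first_out <- dx$day[j]
    }
    end <- min(first_out, p$enroll_end, index + spec$follow_up_days)
    out <- rbind(out, data.frame(
      patient_id = p$patient_id, index_day = index,
      group = if (exposed) "exposed" else "comparator",
      time = end - index, event = as.integer(first_out == end),
      stringsAsFactors = FALSE))
  }
  out
}
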