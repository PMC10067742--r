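#' Configuration for the spontaneous-report simulator
#'
#' Defines a report-level generative model with known ground truth. Drug
#' exposures are independent Bernoulli draws per report (plus a Poisson
#' number of extra uniformly-sampled drugs, emulating polypharmacy), and the
#' event indicator follows a logistic model whose odds multiply the baseline
#' odds by the odds ratio of every present drug and every present
#' interacting pair. Because the model is odds-multiplicative, an injected
#' drug-event odds ratio is exactly the estimand of the downstream reporting
#' odds ratio when the other drugs are null.
#'
#' @param n_reports number of primary reports.
#' @param drug_catalog named numeric vector: exposure probability per report
#'   for each generic drug name; each probability in (0,1).
#' @param polypharmacy_rate mean number of extra drugs per report (Poisson
#'   mean, >= 0), sampled uniformly from the catalog.
#' @param baseline_event_prob event probability for a drug-free report,
#'   in (0,1).
#' @param drug_event_or named numeric vector of per-drug odds ratios (> 0);
#'   drugs not named have OR 1.
#' @param interaction_or data.frame with columns `base`, `concomitant`,
#'   `or` (> 0): the extra odds multiplier applied only when both drugs are
#'   present on a report. May be `NULL`.
#' @param duplicate_rate fraction in [0,1): `floor(duplicate_rate *
#'   n_reports)` reports are re-injected as copies with a new report id and
#'   the same case id, emulating repeat submissions.
#' @param noise_event_prob probability that a report carries an unrelated
#'   background event term ("nausea"), so non-case reports have non-empty
#'   event sets.
#' @param event_term the outcome term written on case reports.
#' @param seed integer seed; generation is a pure function of
#'   (config, seed).
#' @return object of class `sr_sim_config`.
#' @export
sr_sim_config <- function(n_reports,
                          drug_catalog,
                          polypharmacy_rate = 0,
                          baseline_event_prob = 0.05,
                          drug_event_or = NULL,
                          interaction_or = NULL,
                          duplicate_rate = 0,
                          noise_event_prob = 0.3,
                          event_term = "tendinopathy",
                          seed = 1L) {
  if (is.null(names(drug_catalog)) || any(!nzchar(names(drug_catalog)))) {
    stop("invalid 'drug_catalog': must be a named vector of probabilities",
         call. = FALSE)
  }
  check_prob <- function(p, field, open = TRUE) {
    bad <- if (open) any(p <= 0 | p >= 1) else any(p < 0 | p >= 1)
    if (any(is.na(p)) || bad) {
      stop("invalid '", field, "': probabilities must lie in ",
           if (open) "(0,1)" else "[0,1)", call. = FALSE)
    }
  }
  check_prob(drug_catalog, "drug_catalog")
  check_prob(baseline_event_prob, "baseline_event_prob")
  check_prob(duplicate_rate, "duplicate_rate", open = FALSE)
  if (noise_event_prob < 0 || noise_event_prob > 1) {
    stop("invalid 'noise_event_prob': must lie in [0,1]", call. = FALSE)
  }
  if (polypharmacy_rate < 0) {
    stop("invalid 'polypharmacy_rate': must be >= 0", call. = FALSE)
  }
  if (!is.null(drug_event_or)) {
    if (is.null(names(drug_event_or)) || any(is.na(drug_event_or)) ||
        any(drug_event_or <= 0)) {
      stop("invalid 'drug_event_or': named odds ratios, all > 0", call. = FALSE)
    }
    if (!all(names(drug_event_or) %in% names(drug_catalog))) {
      stop("invalid 'drug_event_or': names must appear in drug_catalog",
           call. = FALSE)
    }
  }
  if (!is.null(interaction_or)) {
    stopifnot(is.data.frame(interaction_or),
              all(c("base", "concomitant", "or") %in% names(interaction_or)))
    if (any(is.na(interaction_or$or)) || any(interaction_or$or <= 0)) {
      stop("invalid 'interaction_or': odds ratios must be > 0", call. = FALSE)
    }
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_catalog = drug_catalog,
                 polypharmacy_rate = polypharmacy_rate,
                 baseline_event_prob = baseline_event_prob,
                 drug_event_or = drug_event_or,
                 interaction_or = interaction_or,
                 duplicate_rate = duplicate_rate,
                 noise_event_prob = noise_event_prob,
                 event_term = event_term,
                 seed = as.integer(seed)),
            class = "sr_sim_config")
}

#' Simulate a spontaneous-report set with known ground truth
#'
#' @param config an [sr_sim_config()].
#' @param provenance database label for the generated set.
#' @return list with `reports` (a [report_set] of `n_reports +
#'   floor(duplicate_rate * n_reports)` records) and `truth` (list:
#'   `drug_event_or`, `interaction_or`, `baseline_event_prob`, `event_term`,
#'   and per-primary-report exposure/event matrices used by recovery tests).
#' @export
simulate_reports <- function(config, provenance = "SIM") {
  stopifnot(inherits(config, "sr_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_reports
  drugs <- names(config$drug_catalog)
  k <- length(drugs)

  # independent Bernoulli exposures
  expo <- matrix(stats::runif(n * k) < rep(config$drug_catalog, each = n),
                 nrow = n, ncol = k, dimnames = list(NULL, drugs))
  # polypharmacy: Poisson count of extra uniformly-drawn drugs per report
  if (config$polypharmacy_rate > 0) {
    extra <- stats::rpois(n, config$polypharmacy_rate)
    idx <- rep.int(seq_len(n), extra)
    if (length(idx) > 0L) {
      j <- sample.int(k, length(idx), replace = TRUE)
      expo[cbind(idx, j)] <- TRUE
    }
  }

  # odds-multiplicative event model
  log_odds <- rep(log(config$baseline_event_prob / (1 - config$baseline_event_prob)), n)
  if (!is.null(config$drug_event_or)) {
    for (d in names(config$drug_event_or)) {
      log_odds <- log_odds + expo[, d] * log(config$drug_event_or[[d]])
    }
  }
  if (!is.null(config$interaction_or) && nrow(config$interaction_or) > 0L) {
    for (i in seq_len(nrow(config$interaction_or))) {
      bd <- config$interaction_or$base[i]
      cd <- config$interaction_or$concomitant[i]
      both <- expo[, bd] & expo[, cd]
      log_odds <- log_odds + both * log(config$interaction_or$or[i])
    }
  }
  p_event <- stats::plogis(log_odds)
  event <- stats::runif(n) < p_event
  noise <- stats::runif(n) < config$noise_event_prob

  drug_lists <- apply(expo, 1L, function(row) drugs[row], simplify = FALSE)
  event_lists <- mapply(function(ev, nz) {
    c(if (ev) config$event_term, if (nz) "nausea")
  }, event, noise, SIMPLIFY = FALSE)

  id <- sprintf("R%07d", seq_len(n))
  df <- data.frame(report_id = id, case_id = sprintf("C%07d", seq_len(n)),
                   version = 1L, stringsAsFactors = FALSE)
  df$drugs <- drug_lists
  df$events <- event_lists
  df$age <- round(stats::rnorm(n, 55, 15))
  df$sex <- sample(c("F", "M"), n, replace = TRUE)

  n_dup <- floor(config$duplicate_rate * n)
  if (n_dup > 0L) {
    pick <- sample.int(n, n_dup, replace = FALSE)
    dup <- df[pick, , drop = FALSE]
    dup$report_id <- sprintf("R%07dD", pick)
    df <- rbind(df, dup)
    rownames(df) <- NULL
  }

  truth <- list(drug_event_or = config$drug_event_or,
                interaction_or = config$interaction_or,
                baseline_event_prob = config$baseline_event_prob,
                event_term = config$event_term,
                exposure = expo,
                event = event)
  list(reports = report_set(df, provenance), truth = truth)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
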