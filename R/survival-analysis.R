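#' Kaplan-Meier estimate with daily numbers at risk
#'
#' Product-limit estimation per group via [survival::survfit()], augmented
#' with a day-by-day risk table over `[0, follow_up_days]` — the number of
#' patients still under observation and event-free each day, as shown under
#' a cumulative-incidence plot.
#'
#' @param records data.frame with `time`, `event` and `group` columns
#'   (e.g. from [build_survival()]).
#' @param follow_up_days horizon of the daily risk table; defaults to the
#'   records' `follow_up_days` attribute or `max(time)`.
#' @return object of class `km_estimate`: list with `curves` (data.frame:
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `cum_incidence`) at the event/censoring times, `at_risk` (data.frame:
#'   `group`, `day`, `n_risk` for every integer day), and the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(records, follow_up_days = NULL) {
  stopifnot(nrow(records) > 0L,
            all(c("time", "event", "group") %in% names(records)))
  if (is.null(follow_up_days)) {
    follow_up_days <- attr(records, "follow_up_days") %||% max(records$time)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = records)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(records$group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, n_censor = sm$n.censor,
                       surv = sm$surv, cum_incidence = 1 - sm$surv,
                       stringsAsFactors = FALSE)
  days <- 0:follow_up_days
  at_risk <- do.call(rbind, lapply(sort(unique(records$group)), function(g) {
    sub <- records[records$group == g, , drop = FALSE]
    # at risk at day t: still under observation and event-free, i.e. time >= t
    data.frame(group = g, day = days,
               n_risk = vapply(days, function(t) sum(sub$time >= t), numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(at_risk) <- NULL
  structure(list(curves = curves, at_risk = at_risk, fit = fit),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Log-rank test for two (or more) groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' summed over event times ([survival::survdiff()] with `rho = 0`).
#'
#' @param records data.frame with `time`, `event`, `group`.
#' @return object of class `log_rank_result`: list with `chisq`, `df`, `p`.
#' @export
log_rank <- function(records) {
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  groups <- unique(records$group)
  if (length(groups) < 2L) {
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  }
  if (sum(records$event) < 1L) {
    stop("log-rank test needs at least one event", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  df <- length(sd$n) - 1L
  structure(list(chisq = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE)),
            class = "log_rank_result")
}

#' @export
print.log_rank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards hazard ratio
#'
#' Partial-likelihood fit via [survival::coxph()]. By default a group-only
#' model (`exposed` vs `comparator`); additional covariate columns can be
#' adjusted for. Ties are handled by the Efron method unless `ties =
#' "breslow"` is requested (under which the score test at beta = 0 equals
#' the two-group log-rank statistic on tie-free data).
#'
#' @param records data.frame with `time`, `event`, `group`.
#' @param covariates optional data.frame of additional adjustment columns
#'   (aligned by `patient_id` when both frames carry it, else by row).
#' @param ties `"efron"` or `"breslow"`.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `cox_result`: list with `log_hr`, `hr`, `se`,
#'   `ci_low`, `ci_high`, `p` (Wald), `ties`, and the `coxph` `fit`. The
#'   hazard ratio is for the `exposed` group relative to `comparator`.
#' @export
cox_hr <- function(records, covariates = NULL, ties = c("efron", "breslow"),
                   conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event", "group") %in% names(records)))
  ev_per_group <- tapply(records$event, records$group, sum)
  if (length(ev_per_group) < 2L || any(ev_per_group == 0)) {
    stop("each group needs at least one event for the group-only model ",
         "(monotone partial likelihood otherwise); pool longer follow-up ",
         "or a larger cohort", call. = FALSE)
  }
  dat <- data.frame(time = records$time, event = records$event,
                    exposed = as.numeric(records$group == "exposed"))
  if (!is.null(covariates)) {
    if (!is.null(covariates$patient_id) && !is.null(records$patient_id)) {
      covariates <- covariates[match(records$patient_id, covariates$patient_id),
                               , drop = FALSE]
    }
    add <- covariates[, setdiff(names(covariates),
                                c("patient_id", "group")), drop = FALSE]
    for (nm in names(add)) {
      if (is.character(add[[nm]])) add[[nm]] <- factor(add[[nm]])
    }
    dat <- cbind(dat, add)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = dat,
                         ties = ties)
  est <- summary(fit)$coefficients["exposed", ]
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(log_hr = unname(est["coef"]),
                 hr = unname(exp(est["coef"])),
                 se = unname(est["se(coef)"]),
                 ci_low = unname(exp(est["coef"] - zcrit * est["se(coef)"])),
                 ci_high = unname(exp(est["coef"] + zcrit * est["se(coef)"])),
                 p = unname(est["Pr(>|z|)"]),
                 ties = ties,
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (%s ties): HR = %.3f (95%% CI %.3f-%.3f), Wald p = %.3g\n",
              x$ties, x$hr, x$ci_low, x$ci_high, x$p))
  invisible(x)
}
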