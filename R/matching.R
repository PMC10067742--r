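#' Fit a propensity-score model
#'
#' Additive logistic regression of exposure on the covariates
#' (`stats::glm`, binomial): a convex fit, deterministic given the data.
#' Binary flags enter as supplied; `sex` (and any other character column) is
#' treated as a factor; `patient_id` and `group` are never used as
#' predictors.
#'
#' @param covariates data.frame from [build_covariates()] (or any frame with
#'   a `patient_id` column and predictor columns).
#' @param exposed logical/0-1 vector, one per row: the exposure label. If
#'   omitted, taken from `covariates$group == "exposed"`.
#' @return object of class `propensity_model`: list with the `glm` `fit`,
#'   `scores` (fitted probabilities in (0,1), named by patient id),
#'   `logit_scores`, and `exposed`.
#' @export
fit_propensity <- function(covariates, exposed = NULL) {
  stopifnot(is.data.frame(covariates))
  if (is.null(exposed)) {
    if (is.null(covariates$group)) {
      stop("supply 'exposed' labels or a 'group' column", call. = FALSE)
    }
    exposed <- covariates$group == "exposed"
  }
  exposed <- as.logical(exposed)
  if (length(unique(exposed)) < 2L || min(table(exposed)) < 2L) {
    stop("need at least 2 patients in each arm with non-constant labels",
         call. = FALSE)
  }
  X <- covariates[, setdiff(names(covariates), c("patient_id", "group")),
                  drop = FALSE]
  for (nm in names(X)) {
    if (is.character(X[[nm]])) X[[nm]] <- factor(X[[nm]])
    if (is.factor(X[[nm]]) && nlevels(droplevels(X[[nm]])) < 2L) X[[nm]] <- NULL
  }
  dat <- cbind(.exposed = as.numeric(exposed), X)
  boundary <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.exposed ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("numerically 0 or 1", conditionMessage(w))) boundary <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  scores <- stats::fitted(fit)
  eps <- 1e-8
  if (boundary || any(scores < eps) || any(scores > 1 - eps) || !fit$converged) {
    stop("propensity scores hit the (0,1) boundary (possible perfect ",
         "separation); reduce or coarsen the covariates", call. = FALSE)
  }
  ids <- if (!is.null(covariates$patient_id)) covariates$patient_id
         else as.character(seq_len(nrow(covariates)))
  names(scores) <- ids
  structure(list(fit = fit,
                 scores = scores,
                 logit_scores = stats::qlogis(scores),
                 exposed = stats::setNames(exposed, ids)),
            class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("<propensity_model> %d exposed / %d comparator; score range [%.3f, %.3f]\n",
              sum(x$exposed), sum(!x$exposed), min(x$scores), max(x$scores)))
  invisible(x)
}

#' 1:1 nearest-neighbor propensity matching with a caliper
#'
#' Greedy nearest-neighbor matching without replacement: exposed patients
#' are visited in seeded-random order and each is paired with the closest
#' still-unmatched comparator, provided the distance does not exceed the
#' caliper. By convention a caliper "width" of 0.2 is interpreted on the
#' logit scale as `0.2 * SD(logit score)` pooled over both arms
#' (`caliper_scale = "logit_sd"`); `"raw"` applies the caliper directly to
#' the probability scale.
#'
#' @param model a [fit_propensity()] result, or a list with `scores` and
#'   `exposed` components.
#' @param caliper caliper width (default 0.2).
#' @param caliper_scale `"logit_sd"` or `"raw"`.
#' @param seed integer seed for the greedy visiting order.
#' @return object of class `matched_cohort`: data.frame `pairs`
#'   (`exposed_id`, `comparator_id`, `distance`), plus `caliper` (on the
#'   matching scale), `caliper_scale`, `unmatched_exposed`,
#'   `unmatched_comparator` counts.
#' @export
match_cohort <- function(model, caliper = 0.2,
                         caliper_scale = c("logit_sd", "raw"), seed = 1L) {
  caliper_scale <- match.arg(caliper_scale)
  exposed <- model$exposed
  if (sum(exposed) == 0L || sum(!exposed) == 0L) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  if (caliper_scale == "logit_sd") {
    x <- stats::qlogis(model$scores)
    cal <- caliper * stats::sd(x)
  } else {
    x <- model$scores
    cal <- caliper
  }
  ids <- names(model$scores)
  trt <- which(exposed)
  ctl <- which(!exposed)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  visit <- trt[sample.int(length(trt))]

  # comparators sorted by score; scan outward from the insertion point for
  # the nearest one still available
  o <- order(x[ctl])
  cx <- x[ctl][o]
  cid <- ctl[o]
  avail <- rep(TRUE, length(cid))
  n_avail <- length(cid)
  pairs_e <- character(0); pairs_c <- character(0); pairs_d <- numeric(0)
  for (t in visit) {
    if (n_avail == 0L) break
    xt <- x[t]
    pos <- findInterval(xt, cx)
    lo <- pos; hi <- pos + 1L
    best <- NA_integer_; best_d <- Inf
    while (lo >= 1L || hi <= length(cx)) {
      d_lo <- if (lo >= 1L) abs(xt - cx[lo]) else Inf
      d_hi <- if (hi <= length(cx)) abs(cx[hi] - xt) else Inf
      if (min(d_lo, d_hi) >= best_d) break
      if (d_lo <= d_hi) {
        if (avail[lo] && d_lo < best_d) { best <- lo; best_d <- d_lo }
        lo <- lo - 1L
      } else {
        if (avail[hi] && d_hi < best_d) { best <- hi; best_d <- d_hi }
        hi <- hi + 1L
      }
    }
    if (!is.na(best) && best_d <= cal) {
      avail[best] <- FALSE
      n_avail <- n_avail - 1L
      pairs_e <- c(pairs_e, ids[t])
      pairs_c <- c(pairs_c, ids[cid[best]])
      pairs_d <- c(pairs_d, best_d)
    }
  }
  pairs <- data.frame(exposed_id = pairs_e, comparator_id = pairs_c,
                      distance = pairs_d, stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 caliper = cal,
                 caliper_input = caliper,
                 caliper_scale = caliper_scale,
                 unmatched_exposed = length(trt) - nrow(pairs),
                 unmatched_comparator = length(ctl) - nrow(pairs)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs (caliper %.4f on %s scale); unmatched: %d exposed, %d comparator\n",
              nrow(x$pairs), x$caliper, x$caliper_scale,
              x$unmatched_exposed, x$unmatched_comparator))
  invisible(x)
}

#' Matched patient ids
#'
#' @param matched a [match_cohort()] result.
#' @return character vector of all patient ids appearing in a pair.
#' @export
matched_ids <- function(matched) {
  stopifnot(inherits(matched, "matched_cohort"))
  c(matched$pairs$exposed_id, matched$pairs$comparator_id)
}

#' Covariate balance before and after matching
#'
#' For each covariate, the standardized mean difference
#' `SMD = (mean_exposed - mean_comparator) / pooled SD` is reported on the
#' full sample and on the matched pairs only (the pooled SD is always taken
#' from the pre-match sample, the usual convention, so pre and post are on
#' one scale). Hypothesis tests on the matched sample follow the covariate
#' type: chi-square for binary/categorical flags, and for continuous
#' covariates (age) a Wilcoxon rank-sum or Welch t-test.
#'
#' @param matched a [match_cohort()] result.
#' @param covariates the covariate data.frame used for matching; needs
#'   `patient_id`.
#' @param exposed exposure labels as in [fit_propensity()].
#' @param continuous_test `"wilcoxon"` or `"welch"` for continuous
#'   covariates.
#' @return data.frame of class `balance_report`: `covariate`, `smd_pre`,
#'   `smd_post`, `p_post`, `test`, `zero_variance` flag. Zero-variance
#'   covariates get SMD 0 and are flagged.
#' @export
balance_report <- function(matched, covariates, exposed = NULL,
                           continuous_test = c("wilcoxon", "welch")) {
  stopifnot(inherits(matched, "matched_cohort"), is.data.frame(covariates))
  continuous_test <- match.arg(continuous_test)
  if (nrow(matched$pairs) == 0L) stop("no matched pairs", call. = FALSE)
  if (is.null(exposed)) {
    if (is.null(covariates$group)) {
      stop("supply 'exposed' labels or a 'group' column", call. = FALSE)
    }
    exposed <- covariates$group == "exposed"
  }
  exposed <- as.logical(exposed)
  ids <- covariates$patient_id
  post_keep <- ids %in% matched_ids(matched)

  X <- covariates[, setdiff(names(covariates), c("patient_id", "group")),
                  drop = FALSE]
  rows <- lapply(names(X), function(nm) {
    v <- X[[nm]]
    is_cont <- is.numeric(v) && length(unique(v[!is.na(v)])) > 2L
    if (is.character(v) || is.factor(v)) {
      v <- as.numeric(factor(v)) - 1
      is_cont <- FALSE
    }
    smd <- function(keep) {
      m1 <- mean(v[keep & exposed]); m0 <- mean(v[keep & !exposed])
      s1 <- stats::var(v[exposed]); s0 <- stats::var(v[!exposed])
      pooled <- sqrt((s1 + s0) / 2)
      if (!is.finite(pooled) || pooled == 0) return(c(0, TRUE))
      c((m1 - m0) / pooled, FALSE)
    }
    pre <- smd(rep(TRUE, length(v)))
    post <- smd(post_keep)
    zero_var <- pre[2] == 1
    vp <- v[post_keep]; ep <- exposed[post_keep]
    p_post <- NA_real_
    test <- NA_character_
    if (!zero_var) {
      if (is_cont) {
        if (continuous_test == "wilcoxon") {
          p_post <- suppressWarnings(stats::wilcox.test(vp ~ ep)$p.value)
          test <- "wilcoxon"
        } else {
          p_post <- stats::t.test(vp ~ ep)$p.value
          test <- "welch"
        }
      } else {
        tab <- table(factor(ep, levels = c(FALSE, TRUE)), vp)
        if (all(dim(tab) >= 2L)) {
          p_post <- suppressWarnings(stats::chisq.test(tab)$p.value)
        } else {
          p_post <- 1
        }
        test <- "chisq"
      }
    }
    data.frame(covariate = nm, smd_pre = pre[1], smd_post = post[1],
               p_post = p_post, test = test, zero_variance = zero_var,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("<balance_report>\n")
  print(format(as.data.frame(x), digits = 3))
  invisible(x)
}
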