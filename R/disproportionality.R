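#' Build the 2x2 contingency table for one drug and one event query
#'
#' Cross-tabulates drug exposure against event occurrence over a
#' deduplicated, name-normalized report set:
#' `a` = reports with the drug and the event, `b` = with the drug, no event,
#' `c` = without the drug, with the event, `d` = neither. The table is
#' returned uncorrected; the continuity correction is applied by
#' [ror_statistics()].
#'
#' @param rs a [report_set], deduplicated and normalized.
#' @param drug generic drug name (exact match against the normalized `drugs`
#'   sets).
#' @param query an [event_query].
#' @return object of class `contingency_table`: list with integer cells
#'   `a`, `b`, `c`, `d`, plus `drug`, `query`, and `corrected = FALSE`.
#' @export
contingency <- function(rs, drug, query) {
  stopifnot(inherits(rs, "report_set"))
  exposed <- vapply(rs$drugs, function(v) drug %in% v, logical(1))
  case <- has_event(rs, query)
  contingency_table(
    a = sum(exposed & case), b = sum(exposed & !case),
    c = sum(!exposed & case), d = sum(!exposed & !case),
    drug = drug, query = query$name
  )
}

#' @rdname contingency
#' @param a,b,c,d non-negative cell counts.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_, query = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 drug = drug, query = query,
                 corrected = FALSE, correction_value = 0.5),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> drug=%s query=%s\n", x$drug, x$query))
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Reporting odds ratio with confidence interval and Z score
#'
#' Computes the disproportionality statistics for a 2x2 table. With the
#' Haldane-Anscombe correction (the default, applied to all analyses), 0.5 is
#' added to every cell before computation, so the estimate, interval and Z
#' score are finite even with zero cells. On (possibly corrected) cells:
#' \deqn{ROR = (a/b)/(c/d), \quad SE = \sqrt{1/a + 1/b + 1/c + 1/d}}
#' \deqn{CI_{95} = \exp(\ln ROR \pm 1.96\,SE), \quad Z = \ln(ROR)/SE.}
#' `Z` is the Wald statistic; the implied two-sided normal p-value is also
#' returned. Signal flags use `|Z| >= 1.96`, equivalently a 95% CI excluding
#' 1.
#'
#' @param t a [contingency_table()].
#' @param apply_correction add 0.5 to every cell first (default `TRUE`).
#'   Without correction a zero cell makes the statistics undefined and an
#'   error is raised rather than returning infinities.
#' @param conf_level confidence level for the interval.
#' @return a one-row data.frame of class `signal_result` with columns
#'   `drug`, `a`, `b`, `c`, `d` (pre-correction cells), `ror`, `ci_low`,
#'   `ci_high`, `z`, `p`, `n_exposed_event`, `significant_increase`,
#'   `significant_decrease`.
#' @export
ror_statistics <- function(t, apply_correction = TRUE, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_table"))
  cells <- c(t$a, t$b, t$c, t$d)
  if (apply_correction) {
    cc <- cells + t$correction_value
  } else {
    if (any(cells == 0)) {
      stop("zero cell in uncorrected contingency table: ",
           "ROR/CI/Z are undefined; apply the Haldane-Anscombe correction",
           call. = FALSE)
    }
    cc <- cells
  }
  ror <- (cc[1] / cc[2]) / (cc[3] / cc[4])
  se <- sqrt(sum(1 / cc))
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  lror <- log(ror)
  z <- lror / se
  out <- data.frame(
    drug = t$drug,
    a = cells[1], b = cells[2], c = cells[3], d = cells[4],
    ror = ror,
    ci_low = exp(lror - zcrit * se),
    ci_high = exp(lror + zcrit * se),
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    n_exposed_event = cells[1],
    significant_increase = z >= zcrit,
    significant_decrease = z <= -zcrit,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("signal_result", "data.frame")
  out
}

#' Screen every drug in a report set for disproportionality
#'
#' Computes [ror_statistics()] for each generic drug appearing in the set
#' against the event query, one row per drug with at least `min_cases`
#' drug-with-event reports (the pre-correction `a` cell). The result is the
#' volcano-plot table: ROR on a log scale against `|Z|`, with per-drug report
#' counts for marker sizing.
#'
#' @param rs a [report_set], deduplicated and normalized.
#' @param query an [event_query].
#' @param min_cases minimum pre-correction `a` cell for a drug to be
#'   reported; default 3, a conventional pharmacovigilance floor.
#' @param adjust optionally apply Benjamini-Hochberg adjustment across drugs
#'   (`p_adj` column); off by default, unadjusted Z is what the volcano shows.
#' @return data.frame of class `signal_table`, sorted by `|z|` decreasing,
#'   with the [ror_statistics()] columns plus `n_reports` (reports listing
#'   the drug) and `log10_ror`.
#' @export
screen_drugs <- function(rs, query, min_cases = 3, adjust = FALSE) {
  stopifnot(inherits(rs, "report_set"))
  n <- nrow(rs)
  case <- has_event(rs, query)
  dr <- lapply(rs$drugs, unique)
  len <- lengths(dr)
  drug_flat <- unlist(dr, use.names = FALSE)
  case_flat <- rep(case, len)
  if (length(drug_flat) == 0L) {
    return(empty_signal_table())
  }
  a_tab <- tapply(case_flat, drug_flat, sum)
  n_tab <- tapply(case_flat, drug_flat, length)
  total_cases <- sum(case)
  drugs <- names(a_tab)
  a <- as.numeric(a_tab)
  b <- as.numeric(n_tab) - a
  keep <- a >= min_cases
  if (!any(keep)) return(empty_signal_table())
  rows <- lapply(which(keep), function(i) {
    t <- contingency_table(a[i], b[i], total_cases - a[i],
                           n - n_tab[[i]] - (total_cases - a[i]),
                           drug = drugs[i], query = query$name)
    ror_statistics(t)
  })
  out <- do.call(rbind, rows)
  out$n_reports <- as.numeric(n_tab[keep])
  out$log10_ror <- log10(out$ror)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$z)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signal_table", "data.frame")
  out
}

empty_signal_table <- function() {
  out <- data.frame(
    drug = character(0), a = numeric(0), b = numeric(0), c = numeric(0),
    d = numeric(0), ror = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0), z = numeric(0), p = numeric(0),
    n_exposed_event = numeric(0), significant_increase = logical(0),
    significant_decrease = logical(0), n_reports = numeric(0),
    log10_ror = numeric(0), stringsAsFactors = FALSE
  )
  class(out) <- c("signal_table", "data.frame")
  out
}

#' @export
print.signal_table <- function(x, n = 10, ...) {
  cat(sprintf("<signal_table> %d drugs (|Z| >= 1.96: %d up, %d down)\n",
              nrow(x), sum(x$significant_increase), sum(x$significant_decrease)))
  if (nrow(x) > 0) {
    show <- utils::head(as.data.frame(x)[, c("drug", "a", "ror", "ci_low",
                                             "ci_high", "z", "n_reports")], n)
    print(format(show, digits = 3))
    if (nrow(x) > n) cat(sprintf("  ... and %d more rows\n", nrow(x) - n))
  }
  invisible(x)
}

#' Plot-ready volcano table
#'
#' @param st a `signal_table` from [screen_drugs()] or
#'   [screen_concomitants()].
#' @return data.frame with `drug`, `log10_ror`, `abs_z`, `n_reports` —
#'   x, y and marker-size columns of the volcano plot.
#' @export
volcano_table <- function(st) {
  stopifnot(inherits(st, "signal_table"))
  data.frame(drug = st$drug, log10_ror = st$log10_ror, abs_z = abs(st$z),
             n_reports = st$n_reports, stringsAsFactors = FALSE)
}
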