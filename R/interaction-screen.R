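#' Drug class: a named set of generic names
#'
#' Used to define the base cohort of the concomitant screen (e.g. the
#' fluoroquinolone class).
#'
#' @param name class label.
#' @param members non-empty character vector of generic names.
#' @return object of class `drug_class`.
#' @export
drug_class <- function(name, members) {
  members <- unique(trimws(members))
  members <- members[nzchar(members)]
  if (length(members) == 0L) stop("drug class needs at least one member", call. = FALSE)
  structure(list(name = name, members = members), class = "drug_class")
}

#' 2x2 table for a concomitant drug within a base-class cohort
#'
#' Restricts the report set to reports listing at least one member of the
#' base class, then cross-tabulates presence of the concomitant drug against
#' the event. This is the building block of the confounder screen: the
#' concomitant's effect on the event's reporting odds within base-drug users.
#'
#' @param rs a [report_set], deduplicated and normalized.
#' @param base a [drug_class()].
#' @param concomitant generic name; must not be a member of `base`.
#' @param query an [event_query].
#' @return a [contingency_table()] whose cells sum to the base-cohort size.
#' @export
stratified_contingency <- function(rs, base, concomitant, query) {
  stopifnot(inherits(rs, "report_set"), inherits(base, "drug_class"))
  if (concomitant %in% base$members) {
    stop("concomitant drug '", concomitant,
         "' is a member of the base class '", base$name, "'", call. = FALSE)
  }
  in_base <- vapply(rs$drugs, function(v) any(base$members %in% v), logical(1))
  sub <- rs[in_base, , drop = FALSE]
  with_con <- vapply(sub$drugs, function(v) concomitant %in% v, logical(1))
  case <- has_event(sub$events, query)
  contingency_table(
    a = sum(with_con & case), b = sum(with_con & !case),
    c = sum(!with_con & case), d = sum(!with_con & !case),
    drug = concomitant, query = query$name
  )
}

#' Screen all concomitant drugs within a base-class cohort
#'
#' Within reports containing at least one base-class member, computes
#' corrected ROR statistics for every other drug present in at least
#' `min_cases` base-cohort case reports (pre-correction `a` cell, mirroring
#' the single-drug screen). A drug that significantly lowers the reporting
#' odds of the event among base-drug users is a candidate negative
#' confounder (or protective co-medication).
#'
#' @inheritParams stratified_contingency
#' @param min_cases minimum pre-correction `a` cell; default 3.
#' @return data.frame of classes `pair_signal_table` and `signal_table`,
#'   sorted by `|z|` decreasing, with columns as [screen_drugs()] plus
#'   `base_class` and `database` (the set's provenance label).
#' @export
screen_concomitants <- function(rs, base, query, min_cases = 3) {
  stopifnot(inherits(rs, "report_set"), inherits(base, "drug_class"))
  in_base <- vapply(rs$drugs, function(v) any(base$members %in% v), logical(1))
  sub <- rs[in_base, , drop = FALSE]
  class(sub) <- class(rs)
  attr(sub, "provenance") <- attr(rs, "provenance")
  n <- nrow(sub)
  case <- has_event(sub$events, query)
  dr <- lapply(sub$drugs, function(v) setdiff(unique(v), base$members))
  len <- lengths(dr)
  drug_flat <- unlist(dr, use.names = FALSE)
  out <- empty_signal_table()
  if (length(drug_flat) > 0L) {
    case_flat <- rep(case, len)
    a_tab <- tapply(case_flat, drug_flat, sum)
    n_tab <- tapply(case_flat, drug_flat, length)
    total_cases <- sum(case)
    drugs <- names(a_tab)
    a <- as.numeric(a_tab)
    ntot <- as.numeric(n_tab)
    keep <- a >= min_cases
    if (any(keep)) {
      rows <- lapply(which(keep), function(i) {
        t <- contingency_table(a[i], ntot[i] - a[i], total_cases - a[i],
                               n - ntot[i] - (total_cases - a[i]),
                               drug = drugs[i], query = query$name)
        ror_statistics(t)
      })
      out <- do.call(rbind, rows)
      out$n_reports <- ntot[keep]
      out$log10_ror <- log10(out$ror)
      out <- out[order(-abs(out$z)), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out$base_class <- rep(base$name, nrow(out))
  out$database <- rep(attr(rs, "provenance"), nrow(out))
  class(out) <- c("pair_signal_table", "signal_table", "data.frame")
  out
}

#' Intersect significant concomitant signals across databases
#'
#' Reporting biases differ between spontaneous-report databases; a signal
#' observed independently in all of them is far less likely to be a
#' database-specific artifact. This returns the drugs whose effect is
#' significant in the stated direction — the CI excluding 1 on that side at
#' level `alpha` — in *every* supplied table.
#'
#' @param tables list of `pair_signal_table`s (from [screen_concomitants()])
#'   with at least two distinct `database` labels.
#' @param direction `"decrease"` (protective signals, upper CI bound < 1) or
#'   `"increase"` (lower CI bound > 1).
#' @param alpha two-sided significance level; the one-sided criterion uses
#'   the `alpha/2` tail, i.e. at `alpha = 0.05` a decrease requires
#'   `z <= -1.96`.
#' @return object of class `enrichment_result`: list with `direction`,
#'   `alpha`, `drugs` (character vector ordered by mean ln ROR across
#'   databases, most extreme first) and `evidence` (the supporting rows from
#'   every table).
#' @export
cross_database_enrichment <- function(tables, direction = c("decrease", "increase"),
                                      alpha = 0.05) {
  direction <- match.arg(direction)
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need at least 2 signal tables from distinct databases", call. = FALSE)
  }
  for (t in tables) {
    if (!inherits(t, "signal_table") || is.null(t$database)) {
      stop("each table must be a pair_signal_table with a database label",
           call. = FALSE)
    }
  }
  dbs <- vapply(seq_along(tables), function(i) {
    d <- unique(tables[[i]]$database)
    if (length(d) == 0L) paste0("table", i) else d[1]
  }, character(1))
  if (anyDuplicated(dbs)) {
    stop("signal tables must come from distinct databases; got: ",
         paste(dbs, collapse = ", "), call. = FALSE)
  }
  zcrit <- stats::qnorm(1 - alpha / 2)
  sig_sets <- lapply(tables, function(t) {
    if (nrow(t) == 0L) return(character(0))
    if (direction == "decrease") t$drug[t$z <= -zcrit] else t$drug[t$z >= zcrit]
  })
  common <- Reduce(intersect, sig_sets)
  evidence <- do.call(rbind, lapply(tables, function(t) {
    as.data.frame(t)[t$drug %in% common, , drop = FALSE]
  }))
  if (length(common) > 0L) {
    mean_lror <- tapply(log(evidence$ror), evidence$drug, mean)
    ord <- if (direction == "decrease") order(mean_lror) else order(-mean_lror)
    common <- names(mean_lror)[ord]
    rownames(evidence) <- NULL
  }
  structure(list(direction = direction, alpha = alpha,
                 databases = dbs, drugs = common, evidence = evidence),
            class = "enrichment_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d drug(s) with significant %s in all %d databases (alpha = %g)\n",
              length(x$drugs), x$direction, length(x$databases), x$alpha))
  if (length(x$drugs) > 0) cat("  ", paste(x$drugs, collapse = ", "), "\n")
  invisible(x)
}
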