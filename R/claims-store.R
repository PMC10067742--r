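#' Construct a longitudinal claims store
#'
#' Container for the three claims tables the cohort builder consumes. All
#' days are integer offsets from an arbitrary epoch; enrollment spans are
#' half-open `[start, end)`, and every prescription or diagnosis day must
#' fall inside the owning patient's span.
#'
#' @param patients data.frame: `patient_id`, `age` (years at enrollment),
#'   `sex`, `enroll_start`, `enroll_end`.
#' @param prescriptions data.frame: `patient_id`, `day`, `code`, `route`,
#'   and optionally `days_supplied`.
#' @param diagnoses data.frame: `patient_id`, `day`, `code`.
#' @param validate check the within-enrollment invariant (default `TRUE`).
#' @return object of class `claims_store`.
#' @export
claims_store <- function(patients, prescriptions, diagnoses, validate = TRUE) {
  stopifnot(is.data.frame(patients), is.data.frame(prescriptions),
            is.data.frame(diagnoses))
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0L) {
      stop(what, " table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(patients, c("patient_id", "age", "sex", "enroll_start", "enroll_end"),
       "patients")
  need(prescriptions, c("patient_id", "day", "code", "route"), "prescriptions")
  need(diagnoses, c("patient_id", "day", "code"), "diagnoses")
  if (anyDuplicated(patients$patient_id)) {
    stop("patient_id must be unique in the patients table", call. = FALSE)
  }
  if (!"days_supplied" %in% names(prescriptions)) {
    prescriptions$days_supplied <- rep(NA_integer_, nrow(prescriptions))
  }
  if (validate) {
    check_span <- function(df, what) {
      if (nrow(df) == 0L) return(invisible())
      i <- match(df$patient_id, patients$patient_id)
      if (anyNA(i)) stop(what, " table references unknown patient ids", call. = FALSE)
      bad <- df$day < patients$enroll_start[i] | df$day >= patients$enroll_end[i]
      if (any(bad)) {
        stop(sum(bad), " ", what, " record(s) fall outside the owning ",
             "patient's enrollment span", call. = FALSE)
      }
    }
    check_span(prescriptions, "prescription")
    check_span(diagnoses, "diagnosis")
    if (any(patients$enroll_end <= patients$enroll_start)) {
      stop("enrollment spans must satisfy start < end", call. = FALSE)
    }
  }
  structure(list(patients = patients,
                 prescriptions = prescriptions,
                 diagnoses = diagnoses),
            class = "claims_store")
}

#' @export
print.claims_store <- function(x, ...) {
  cat(sprintf("<claims_store> %d patients, %d prescriptions, %d diagnoses\n",
              nrow(x$patients), nrow(x$prescriptions), nrow(x$diagnoses)))
  invisible(x)
}

#' Read a claims store from a directory of delimited tables
#'
#' Expects `patients.tsv`, `prescriptions.tsv`, `diagnoses.tsv` with the
#' columns documented in [claims_store()].
#'
#' @param dir directory path.
#' @param sep field delimiter.
#' @return a [claims_store].
#' @export
read_claims <- function(dir, sep = "\t") {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  }
  claims_store(rd("patients.tsv"), rd("prescriptions.tsv"), rd("diagnoses.tsv"))
}

#' Write a claims store to a directory of delimited tables
#'
#' @param cs a [claims_store].
#' @param dir output directory (created if absent).
#' @param sep field delimiter.
#' @export
write_claims <- function(cs, dir, sep = "\t") {
  stopifnot(inherits(cs, "claims_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = sep, quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wr(cs$patients, "patients.tsv")
  wr(cs$prescriptions, "prescriptions.tsv")
  wr(cs$diagnoses, "diagnoses.tsv")
  invisible(dir)
}
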