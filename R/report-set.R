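#' Construct a spontaneous-report set
#'
#' A `report_set` holds one row per adverse-event report, with the drug and
#' event fields as list-columns of character vectors. It is the container
#' consumed by the disproportionality and interaction screens.
#'
#' @param reports data.frame with columns `report_id`, `case_id`, `version`
#'   (integer), `drugs` (list of character vectors or ";"-separated strings),
#'   `events` (likewise), and optionally `age`, `sex`.
#' @param provenance character label naming the source database
#'   (e.g. `"FAERS"`); carried through to enrichment so that evidence from
#'   distinct databases can be told apart.
#' @return object of class `report_set`: the data.frame plus attributes
#'   `provenance`, `deduplicated` and `normalized` (both `FALSE` on
#'   construction).
#' @export
report_set <- function(reports, provenance = "unknown") {
  stopifnot(is.data.frame(reports))
  required <- c("report_id", "case_id", "version", "drugs", "events")
  missing_cols <- setdiff(required, names(reports))
  if (length(missing_cols) > 0L) {
    stop("report table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"age" %in% names(reports)) reports$age <- NA_real_
  if (!"sex" %in% names(reports)) reports$sex <- NA_character_
  reports$report_id <- as.character(reports$report_id)
  reports$case_id <- as.character(reports$case_id)
  reports$version <- as.integer(reports$version)
  if (anyDuplicated(reports$report_id)) {
    stop("report_id must be unique within a report set", call. = FALSE)
  }
  reports$drugs <- as_term_list(reports$drugs)
  reports$events <- as_term_list(reports$events)
  rownames(reports) <- NULL
  structure(reports,
            provenance = provenance,
            deduplicated = FALSE,
            normalized = FALSE,
            class = c("report_set", "data.frame"))
}

# Split ";"-separated fields into character vectors; pass list-columns through.
as_term_list <- function(x, sep = ";") {
  if (is.list(x)) {
    lapply(x, function(v) {
      v <- trimws(as.character(v))
      v[nzchar(v)]
    })
  } else {
    lapply(strsplit(as.character(x), sep, fixed = TRUE), function(v) {
      if (length(v) == 1L && is.na(v)) return(character(0))
      v <- trimws(v)
      v[nzchar(v)]
    })
  }
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d reports from %s (deduplicated: %s, normalized: %s)\n",
              nrow(x), attr(x, "provenance"),
              attr(x, "deduplicated"), attr(x, "normalized")))
  cat(sprintf("  distinct case ids: %d\n", length(unique(x$case_id))))
  invisible(x)
}

#' Read spontaneous reports from a delimited text file
#'
#' The expected schema is one row per report with columns `report_id`,
#' `case_id`, `version`, `drugs`, `events`, `age`, `sex`; the multi-valued
#' `drugs` and `events` fields are `";"`-separated within a cell.
#'
#' @param path file path.
#' @param provenance database label attached to the resulting set.
#' @param sep field delimiter (default tab).
#' @param term_sep delimiter inside the multi-valued fields.
#' @return a [report_set].
#' @export
read_reports <- function(path, provenance = "unknown", sep = "\t", term_sep = ";") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (nrow(df) == 0L) {
    warning("empty report file: ", path, call. = FALSE)
    df <- data.frame(report_id = character(0), case_id = character(0),
                     version = integer(0), drugs = character(0),
                     events = character(0), age = numeric(0),
                     sex = character(0), stringsAsFactors = FALSE)
    return(report_set(df, provenance))
  }
  required <- c("report_id", "case_id", "version", "drugs", "events")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("report table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$version <- as.integer(df$version)
  if ("age" %in% names(df)) df$age <- as.numeric(df$age)
  df$drugs <- as_term_list(df$drugs, term_sep)
  df$events <- as_term_list(df$events, term_sep)
  report_set(df, provenance)
}

#' Write a report set to a delimited text file
#'
#' Inverse of [read_reports()]: list-columns are joined with `term_sep`.
#'
#' @param rs a [report_set].
#' @param path output file path.
#' @param sep field delimiter.
#' @param term_sep delimiter for the multi-valued fields.
#' @export
write_reports <- function(rs, path, sep = "\t", term_sep = ";") {
  stopifnot(inherits(rs, "report_set"))
  df <- as.data.frame(rs)
  df$drugs <- vapply(rs$drugs, paste, character(1), collapse = term_sep)
  df$events <- vapply(rs$events, paste, character(1), collapse = term_sep)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Drug-name map: raw names to unified generic names
#'
#' Emulates the mapping of trade names, abbreviations and salts to unified
#' generic names. Lookup is case-insensitive.
#'
#' @param raw character vector of raw names.
#' @param generic character vector of generic names, same length.
#' @param unmapped policy for names absent from the map: `"keep"` retains
#'   them verbatim (default; dropping silently would bias denominators) or
#'   `"drop"` removes them.
#' @return object of class `drug_map`.
#' @export
drug_map <- function(raw, generic, unmapped = c("keep", "drop")) {
  unmapped <- match.arg(unmapped)
  stopifnot(length(raw) == length(generic))
  key <- tolower(trimws(raw))
  if (anyDuplicated(key)) stop("duplicate raw names in drug map", call. = FALSE)
  structure(list(table = stats::setNames(trimws(generic), key),
                 unmapped = unmapped),
            class = "drug_map")
}

#' Read a drug map from two-column delimited text
#'
#' @param path file with columns `raw`, `generic`.
#' @param unmapped unmapped-name policy, see [drug_map()].
#' @param sep field delimiter.
#' @return a [drug_map].
#' @export
read_drug_map <- function(path, unmapped = c("keep", "drop"), sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("raw", "generic") %in% names(df))) {
    stop("drug map file must have columns 'raw' and 'generic'", call. = FALSE)
  }
  drug_map(df$raw, df$generic, unmapped = match.arg(unmapped))
}

#' Event query: a term set defining the outcome
#'
#' Stands in for the narrow scope of a standardized MedDRA query: a report is
#' a case iff any of its event terms matches any query term exactly after
#' trimming and case-folding.
#'
#' @param name query label.
#' @param terms non-empty character vector of event terms.
#' @return object of class `event_query`.
#' @export
event_query <- function(name, terms) {
  terms <- unique(tolower(trimws(terms)))
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("event query needs a non-empty term set", call. = FALSE)
  structure(list(name = name, terms = terms), class = "event_query")
}

#' Read an event query from one-column delimited text
#'
#' @param path file with one term per line (a header line `term` is allowed).
#' @param name query label (defaults to the file name).
#' @return an [event_query].
#' @export
read_event_query <- function(path, name = basename(path)) {
  terms <- readLines(path, warn = FALSE)
  terms <- terms[nzchar(trimws(terms))]
  if (length(terms) > 0L && tolower(trimws(terms[1])) == "term") terms <- terms[-1]
  event_query(name, terms)
}

#' Normalize drug names to unified generic names
#'
#' Maps every raw drug name through the [drug_map()]; two trade names of one
#' generic collapse to a single entry. Unmapped names are kept verbatim or
#' dropped per the map's policy; either way they are recorded in the
#' `normalization` attribute of the result. Idempotent when generic names map
#' to themselves (or are absent from the map under the keep policy).
#'
#' @param rs a [report_set].
#' @param map a [drug_map].
#' @return a new `report_set` with the `drugs` column normalized and the
#'   `normalized` attribute set.
#' @export
normalize_drugs <- function(rs, map) {
  stopifnot(inherits(rs, "report_set"), inherits(map, "drug_map"))
  tab <- map$table
  keep <- identical(map$unmapped, "keep")
  unmapped_seen <- character(0)
  rs$drugs <- lapply(rs$drugs, function(v) {
    if (length(v) == 0L) return(v)
    key <- tolower(trimws(v))
    hit <- tab[key]
    miss <- is.na(hit)
    if (any(miss)) {
      unmapped_seen <<- c(unmapped_seen, v[miss])
      hit[miss] <- if (keep) v[miss] else NA_character_
    }
    unique(unname(hit[!is.na(hit)]))
  })
  attr(rs, "normalized") <- TRUE
  attr(rs, "normalization") <- list(
    policy = map$unmapped,
    unmapped = sort(unique(unmapped_seen))
  )
  rs
}

#' Deduplicate a report set by case id
#'
#' Spontaneous-report databases contain repeat submissions of one case.
#' For each `case_id` the record with the highest `version` is kept, ties
#' broken by the lexicographically greatest `report_id` — a simple,
#' deterministic stand-in for database-specific deduplication procedures.
#'
#' @param rs a [report_set].
#' @return a new `report_set` with one record per case id, the `deduplicated`
#'   attribute set, and the number of removed records in the `removed`
#'   attribute.
#' @export
deduplicate_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  o <- order(rs$case_id, rs$version, rs$report_id,
             method = "radix", decreasing = c(FALSE, TRUE, TRUE))
  keep_idx <- o[!duplicated(rs$case_id[o])]
  out <- rs[sort(keep_idx), , drop = FALSE]
  rownames(out) <- NULL
  removed <- nrow(rs) - nrow(out)
  attr(out, "provenance") <- attr(rs, "provenance")
  attr(out, "normalized") <- attr(rs, "normalized")
  attr(out, "normalization") <- attr(rs, "normalization")
  attr(out, "deduplicated") <- TRUE
  attr(out, "removed") <- removed
  class(out) <- class(rs)
  out
}

#' Does each report match the event query?
#'
#' A report is a case iff its event-term set intersects the query's term set;
#' matching is exact on trimmed, case-folded strings (no ontology traversal).
#'
#' @param rs a [report_set] (or a single record from one).
#' @param query an [event_query].
#' @return logical vector, one element per report.
#' @export
has_event <- function(rs, query) {
  stopifnot(inherits(query, "event_query"))
  events <- if (inherits(rs, "report_set")) rs$events else rs
  vapply(events, function(ev) {
    length(ev) > 0L && any(tolower(trimws(ev)) %in% query$terms)
  }, logical(1))
}
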