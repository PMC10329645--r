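#' Collar-history records
#'
#' Constructs a validated table of collar histories, one row per tracked
#' animal: identifier, sex, age class at collaring, monitoring interval,
#' fate and (for deaths) cause. This is a fates-only data model: an animal
#' is "on air" on every day from `start_date` through `end_date` inclusive,
#' and the final day (death or censoring day) counts as a monitored day.
#'
#' @param wolf_id character; unique animal identifiers (e.g. `"W05-2270"`).
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param age_class age class at collaring: `"pup"`, `"yearling"`, `"adult"`.
#' @param start_date,end_date `Date` (or coercible); monitoring interval,
#'   `start_date < end_date`.
#' @param fate `"dead"` or `"censored"`.
#' @param cause `"human"`, `"natural"`, `"unknown"` for deaths;
#'   `"not_applicable"` for censored animals (the default fills this in).
#' @return A `data.frame` of class `"wolf_records"`.
#' @seealso [read_wolf_records()], [validate_wolf_records()]
#' @examples
#' wolf_records(wolf_id = "W10-001", sex = "female", age_class = "adult",
#'              start_date = "2010-01-01", end_date = "2010-12-31",
#'              fate = "dead", cause = "human")
#' @export
wolf_records <- function(wolf_id, sex, age_class, start_date, end_date,
                         fate, cause = NULL) {
  n <- length(wolf_id)
  if (is.null(cause))
    cause <- ifelse(fate == "censored", "not_applicable", "unknown")
  df <- data.frame(
    wolf_id    = as.character(wolf_id),
    sex        = tolower(as.character(sex)),
    age_class  = tolower(as.character(age_class)),
    start_date = as.Date(start_date),
    end_date   = as.Date(end_date),
    fate       = tolower(as.character(fate)),
    cause      = tolower(as.character(cause)),
    stringsAsFactors = FALSE)
  class(df) <- c("wolf_records", "data.frame")
  df <- validate_wolf_records(df)
  df
}

.sex_levels   <- c("male", "female", "unknown")
.age_levels   <- c("pup", "yearling", "adult")
.fate_levels  <- c("dead", "censored")
.cause_levels <- c("human", "natural", "unknown", "not_applicable")

.study_span <- c(as.Date("2004-01-01"), as.Date("2019-12-31"))

#' Validate collar-history records
#'
#' Checks the schema and invariants of a [wolf_records()] table. Validation
#' is total: every offending row is reported with its row number, and no
#' row is silently dropped. Hard errors are malformed dates, unknown codes,
#' `start_date >= end_date`, a cause inconsistent with the fate
#' (`not_applicable` if and only if censored), and duplicate identifiers
#' with overlapping monitoring intervals. Records outside the 2004--2019
#' study span, and pups collared implausibly early in the year (before
#' July 1; wolf pups are born in April and cannot carry a collar within
#' weeks of birth), draw warnings only.
#'
#' @param records a `wolf_records` data.frame (or compatible).
#' @return The validated records, invisibly classed `"wolf_records"`.
#' @export
validate_wolf_records <- function(records) {
  req <- c("wolf_id", "sex", "age_class", "start_date", "end_date",
           "fate", "cause")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  records$start_date <- as.Date(records$start_date)
  records$end_date <- as.Date(records$end_date)

  problems <- character(0)
  bad <- function(rows, msg)
    if (length(rows)) sprintf("row %d: %s", rows, msg) else character(0)

  problems <- c(problems,
    bad(which(is.na(records$start_date)), "unparseable start_date"),
    bad(which(is.na(records$end_date)), "unparseable end_date"),
    bad(which(!records$sex %in% .sex_levels), "unknown sex code"),
    bad(which(!records$age_class %in% .age_levels), "unknown age_class code"),
    bad(which(!records$fate %in% .fate_levels), "unknown fate code"),
    bad(which(!records$cause %in% .cause_levels), "unknown cause code"))
  ok_dates <- !is.na(records$start_date) & !is.na(records$end_date)
  problems <- c(problems,
    bad(which(ok_dates & records$start_date >= records$end_date),
        "start_date must precede end_date"),
    bad(which(records$fate == "censored" & records$cause != "not_applicable"),
        "censored record must have cause = not_applicable"),
    bad(which(records$fate == "dead" & records$cause == "not_applicable"),
        "dead record must have a cause (human/natural/unknown)"))

  # duplicate ids are fine (recaptures) unless their intervals overlap
  if (anyDuplicated(records$wolf_id)) {
    for (id in unique(records$wolf_id[duplicated(records$wolf_id)])) {
      rows <- which(records$wolf_id == id)
      o <- order(records$start_date[rows])
      rows <- rows[o]
      overl <- rows[-length(rows)][
        records$end_date[rows[-length(rows)]] >= records$start_date[rows[-1]]]
      problems <- c(problems,
        bad(overl, sprintf("wolf_id '%s' has overlapping intervals", id)))
    }
  }
  if (length(problems))
    stop("invalid collar-history records:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  out_of_span <- which(ok_dates &
    (records$start_date < .study_span[1] | records$end_date > .study_span[2]))
  if (length(out_of_span))
    warning(length(out_of_span),
            " record(s) fall outside the 2004-2019 study span (rows ",
            paste(out_of_span, collapse = ", "), ")")
  impl <- which(implausible_pup(records))
  if (length(impl))
    warning("pup record(s) collared before July 1 of the start year (rows ",
            paste(impl, collapse = ", "),
            "); consider reclassify_implausible_pups()")
  class(records) <- unique(c("wolf_records", class(records)))
  invisible(records)
}

implausible_pup <- function(records) {
  cutoff <- as.Date(sprintf("%s-07-01", format(records$start_date, "%Y")))
  records$age_class == "pup" & records$start_date < cutoff
}

#' Reclassify implausibly early pup collarings as yearlings
#'
#' A pup whose monitoring starts before July 1 of its start year cannot
#' have been a collarable pup (pups are born in April); such records are
#' reclassified as yearlings. Each reclassification is reported via
#' `message()` and recorded in the `"reclassified"` attribute.
#'
#' @param records a `wolf_records` table.
#' @return The records with implausible pups recoded to `"yearling"`;
#'   attribute `"reclassified"` holds the affected `wolf_id`s.
#' @examples
#' r <- wolf_records("W05-2270", "unknown", "pup",
#'                   "2005-05-06", "2006-03-01", "censored")
#' reclassify_implausible_pups(r)
#' @export
reclassify_implausible_pups <- function(records) {
  idx <- which(implausible_pup(records))
  if (length(idx)) {
    for (i in idx)
      message(sprintf(
        "reclassifying %s: pup collared %s (before July 1) -> yearling",
        records$wolf_id[i], format(records$start_date[i])))
    records$age_class[idx] <- "yearling"
  }
  attr(records, "reclassified") <- records$wolf_id[idx]
  records
}

#' Read collar histories from CSV
#'
#' Reads the canonical collar-history schema (columns `wolf_id, sex,
#' age_class, start_date, end_date, fate, cause`; ISO-8601 dates; header
#' row), normalizes demographic codes case-insensitively, and validates.
#' Files with other column names can be adapted through `col_map`, a named
#' character vector mapping canonical names to the file's column names,
#' e.g. `c(wolf_id = "ID", start_date = "CaptureDate", ...)`.
#'
#' @param path path to a CSV file.
#' @param col_map optional named character vector; names are canonical
#'   column names, values the file's column names.
#' @return A validated `wolf_records` data.frame.
#' @seealso [write_wolf_records()]
#' @export
read_wolf_records <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src))
      stop("col_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    names(raw)[match(unname(col_map), names(raw))] <- names(col_map)
  }
  names(raw) <- tolower(names(raw))
  for (col in c("start_date", "end_date")) {
    if (!col %in% names(raw)) stop("missing required column: ", col)
    parsed <- as.Date(raw[[col]], format = "%Y-%m-%d")
    badrows <- which(is.na(parsed) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(badrows))
      stop("malformed ", col, " (expected ISO-8601) in row(s) ",
           paste(badrows, collapse = ", "))
    raw[[col]] <- parsed
  }
  for (col in c("sex", "age_class", "fate", "cause"))
    if (col %in% names(raw)) raw[[col]] <- tolower(trimws(raw[[col]]))
  if (!"cause" %in% names(raw))
    raw$cause <- ifelse(raw$fate == "censored", "not_applicable", "unknown")
  class(raw) <- c("wolf_records", "data.frame")
  validate_wolf_records(raw)
}

#' Write collar histories to CSV
#'
#' Writes the canonical schema with ISO-8601 dates; `read_wolf_records()`
#' round-trips the result field-for-field.
#'
#' @param records a `wolf_records` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wolf_records <- function(records, path) {
  out <- as.data.frame(records)[, c("wolf_id", "sex", "age_class",
                                    "start_date", "end_date", "fate", "cause")]
  out$start_date <- format(out$start_date, "%Y-%m-%d")
  out$end_date <- format(out$end_date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
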