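# Stay-record schema, CSV I/O and validation.
#
# One row per inpatient case. A missing discharge date means the case was
# still in hospital at the window end (administratively censored); such
# cases occupy the census until the window end but carry no usable PCCL,
# because case-level complexity is only graded at discharge.

STAY_COLUMNS <- c("case_id", "hospital_id", "hospital_type", "admit_date",
                  "discharge_date", "died", "pccl", "age", "sex")

#' Hospital type taxonomy
#'
#' The five general-hospital classes used throughout the package, ordered
#' from largest to smallest: university, tertiary care, and large / medium /
#' small basic hospitals.
#'
#' @return Character vector of the five type labels.
#' @export
hospital_types <- function() {
  c("university", "tertiary", "large_basic", "medium_basic", "small_basic")
}

# Coerce a data frame to the canonical stays tibble; adds the `censored`
# column (absent discharge date) when missing. Internal.
as_stays <- function(df) {
  df <- tibble::as_tibble(df)
  missing_cols <- setdiff(STAY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("stay table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$admit_date <- as.Date(df$admit_date)
  df$discharge_date <- as.Date(df$discharge_date)
  df$died <- as.logical(df$died)
  df$pccl <- as.integer(df$pccl)
  df$age <- as.integer(df$age)
  if (!"censored" %in% names(df)) {
    df$censored <- is.na(df$discharge_date)
  }
  df[, c(STAY_COLUMNS, "censored")]
}

#' Read and window-censor a stay-record table
#'
#' Reads a comma-delimited stay table (UTF-8, header
#' `case_id,hospital_id,hospital_type,admit_date,discharge_date,died,pccl,age,sex`,
#' ISO-8601 dates, booleans as 0/1, absent values as empty strings) and
#' applies the window semantics:
#'
#' * rows whose stay does not overlap the window (admitted after its end,
#'   or discharged before its start) are dropped, with a message giving the
#'   count;
#' * discharge dates after the window end are censored to absent and the
#'   row is flagged `censored = TRUE`; a censored row cannot carry a death
#'   flag (the death, if any, lies outside the window);
#' * malformed rows (unparseable dates, discharge before admission, unknown
#'   hospital type, invalid PCCL / age / sex, duplicated case ids) abort
#'   with line-numbered messages.
#'
#' @param path Path to the CSV file.
#' @param window A [calendar_window()].
#' @return A tibble of validated stay records with an extra logical
#'   `censored` column.
#' @seealso [write_stays()], [validate_stays()]
#' @export
read_stays <- function(path, window) {
  stopifnot(inherits(window, "calendar_window"))
  if (!file.exists(path)) {
    stop("stay file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (!identical(names(raw), STAY_COLUMNS)) {
    stop("unexpected header; expected: ",
         paste(STAY_COLUMNS, collapse = ","), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    out <- tibble::tibble(
      case_id = character(), hospital_id = character(),
      hospital_type = character(), admit_date = as.Date(character()),
      discharge_date = as.Date(character()), died = logical(),
      pccl = integer(), age = integer(), sex = character(),
      censored = logical()
    )
    return(out)
  }

  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  blank <- function(x) !nzchar(x)
  parse_date <- function(x) as.Date(ifelse(blank(x), NA, x),
                                    format = "%Y-%m-%d")
  parse_int <- function(x) suppressWarnings(as.integer(
    ifelse(blank(x), NA, x)))

  admit <- parse_date(raw$admit_date)
  discharge <- parse_date(raw$discharge_date)
  died <- parse_int(raw$died)
  pccl <- parse_int(raw$pccl)
  age <- parse_int(raw$age)

  errs <- character()
  add_err <- function(bad, what) {
    if (any(bad)) {
      errs <<- c(errs, sprintf("line %d: %s", line[bad], what))
    }
  }
  add_err(is.na(admit), "malformed or missing admit_date")
  add_err(!blank(raw$discharge_date) & is.na(discharge),
          "malformed discharge_date")
  add_err(!is.na(admit) & !is.na(discharge) & discharge < admit,
          "discharge_date before admit_date")
  add_err(!raw$hospital_type %in% hospital_types(),
          "unknown hospital_type")
  add_err(is.na(died) | !died %in% c(0L, 1L), "died must be 0 or 1")
  add_err(!blank(raw$pccl) & (is.na(pccl) | pccl < 0L | pccl > 4L),
          "pccl must be an integer in 0..4")
  add_err(is.na(age) | age < 0L, "age must be a non-negative integer")
  add_err(!raw$sex %in% c("female", "male"), "sex must be female or male")
  add_err(died == 1L & blank(raw$discharge_date),
          "died = 1 requires a discharge_date")
  dup <- duplicated(raw$case_id) | duplicated(raw$case_id, fromLast = TRUE)
  if (any(dup)) {
    errs <- c(errs, sprintf("duplicate case_id: %s",
                            unique(raw$case_id[dup])))
  }
  if (length(errs) > 0) {
    stop("invalid stay table:\n  ",
         paste(utils::head(errs, 20), collapse = "\n  "),
         if (length(errs) > 20) sprintf("\n  ... and %d more",
                                        length(errs) - 20),
         call. = FALSE)
  }

  out <- tibble::tibble(
    case_id = raw$case_id, hospital_id = raw$hospital_id,
    hospital_type = raw$hospital_type, admit_date = admit,
    discharge_date = discharge, died = died == 1L, pccl = pccl,
    age = age, sex = raw$sex
  )

  # Drop rows with no overlap with the window.
  out_of_window <- out$admit_date > window$end |
    (!is.na(out$discharge_date) & out$discharge_date < window$start)
  if (any(out_of_window)) {
    message(sum(out_of_window),
            " record(s) outside the study window were dropped")
    out <- out[!out_of_window, ]
  }

  # Censor discharges beyond the window end.
  beyond <- !is.na(out$discharge_date) & out$discharge_date > window$end
  out$discharge_date[beyond] <- as.Date(NA)
  out$died[beyond] <- FALSE
  out$censored <- is.na(out$discharge_date)
  out
}

#' Write a stay-record table
#'
#' Serializes stay records to the delimited format [read_stays()] accepts:
#' ISO-8601 dates, `died` as 0/1, absent fields as empty strings. The
#' internal `censored` flag is not written; it is implied by an absent
#' discharge date.
#'
#' @param records A stay tibble (as returned by [read_stays()] or
#'   [simulate_population()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stays <- function(records, path) {
  records <- as_stays(records)
  out <- records[, STAY_COLUMNS]
  out$admit_date <- format(out$admit_date, "%Y-%m-%d")
  out$discharge_date <- ifelse(is.na(out$discharge_date), NA,
                               format(out$discharge_date, "%Y-%m-%d"))
  out$died <- as.integer(out$died)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Validate a stay-record table
#'
#' Checks the stay-record invariants and returns a report rather than
#' failing. Errors: discharge before admission; PCCL outside 0..4; death
#' flagged without a discharge date; duplicated case ids; unknown hospital
#' type; negative age. Warnings: a censored (undischarged) case carrying a
#' PCCL, and a discharged case without one — complexity grading happens at
#' discharge, so PCCL should exist exactly for cases discharged within the
#' window.
#'
#' @param records A stay tibble.
#' @return A tibble with columns `severity` (`"error"`/`"warning"`),
#'   `rule`, `case_id` and `message`; zero rows when the table is fully
#'   valid.
#' @export
validate_stays <- function(records) {
  records <- as_stays(records)
  entry <- function(severity, rule, case_id, msg) {
    tibble::tibble(severity = severity, rule = rule,
                   case_id = as.character(case_id), message = msg)
  }
  report <- list()
  bad <- !is.na(records$discharge_date) &
    records$discharge_date < records$admit_date
  if (any(bad)) {
    report <- c(report, list(entry(
      "error", "discharge_before_admit", records$case_id[bad],
      "discharge_date before admit_date")))
  }
  bad <- !is.na(records$pccl) & (records$pccl < 0L | records$pccl > 4L)
  if (any(bad)) {
    report <- c(report, list(entry(
      "error", "pccl_range", records$case_id[bad],
      "pccl outside 0..4")))
  }
  bad <- records$died & is.na(records$discharge_date)
  if (any(bad)) {
    report <- c(report, list(entry(
      "error", "death_without_discharge", records$case_id[bad],
      "died = TRUE requires a discharge_date")))
  }
  bad <- !records$hospital_type %in% hospital_types()
  if (any(bad)) {
    report <- c(report, list(entry(
      "error", "unknown_hospital_type", records$case_id[bad],
      "unknown hospital_type")))
  }
  bad <- is.na(records$age) | records$age < 0L
  if (any(bad)) {
    report <- c(report, list(entry(
      "error", "age_negative", records$case_id[bad],
      "age must be a non-negative integer")))
  }
  dup <- duplicated(records$case_id) |
    duplicated(records$case_id, fromLast = TRUE)
  if (any(dup)) {
    report <- c(report, list(entry(
      "error", "duplicate_case_id", unique(records$case_id[dup]),
      "case_id not unique")))
  }
  bad <- is.na(records$discharge_date) & !is.na(records$pccl)
  if (any(bad)) {
    report <- c(report, list(entry(
      "warning", "pccl_on_censored_case", records$case_id[bad],
      "censored case carries a pccl; complexity is graded at discharge")))
  }
  bad <- !is.na(records$discharge_date) & is.na(records$pccl)
  if (any(bad)) {
    report <- c(report, list(entry(
      "warning", "pccl_missing_on_discharged_case", records$case_id[bad],
      "discharged case has no pccl")))
  }
  if (length(report) == 0) {
    return(entry(character(), character(), character(), character()))
  }
  dplyr::bind_rows(report)
}

#' Hospital metadata from a stay table
#'
#' Extracts the distinct hospital id / hospital type pairs appearing in a
#' stay table, as used by the aggregation functions to map panel rows to
#' hospital types.
#'
#' @param records A stay tibble.
#' @return A tibble with columns `hospital_id`, `hospital_type`.
#' @export
hospital_table <- function(records) {
  records <- as_stays(records)
  out <- dplyr::distinct(records, .data$hospital_id, .data$hospital_type)
  if (anyDuplicated(out$hospital_id) > 0) {
    stop("hospital_id mapped to more than one hospital_type", call. = FALSE)
  }
  dplyr::arrange(out, .data$hospital_id)
}
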