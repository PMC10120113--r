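#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical table schemas for the delimited exchange format. The data
# dictionary shipped at inst/extdata/data_dictionary.md mirrors this list.
CLAIMS_TABLES <- c("members", "enrollment", "diagnoses", "prescriptions",
                   "institutions")

CLAIMS_SCHEMAS <- list(
  members = c(member_id = "character", birth_year_month = "character",
              sex = "character"),
  enrollment = c(member_id = "character", start_date = "Date",
                 end_date = "Date"),
  diagnoses = c(member_id = "character", claim_date = "Date",
                icd10_code = "character", setting = "character"),
  prescriptions = c(member_id = "character", dispense_date = "Date",
                    generic_name = "character", days_supplied = "integer",
                    bedtime_flag = "logical", prn_flag = "logical",
                    institution_id = "character", setting = "character"),
  institutions = c(institution_id = "character",
                   primary_department = "character", n_beds = "integer")
)

SETTINGS <- c("outpatient", "inpatient")
SEXES <- c("male", "female")
DEPARTMENTS <- c("psychiatry", "other")

#' Assemble a validated claims dataset
#'
#' Bundles the five claims tables (members, enrollment intervals, diagnosis
#' claims, prescription claims, institutions) into a single dataset object
#' that all downstream stages consume. Validation enforces the domain
#' invariants: unique member ids, valid birth year-months, ordered closed
#' enrollment intervals, ICD-10 category codes of the form letter + 2-3
#' digits, positive days supplied, and referential integrity (every claim's
#' `member_id` has a member row; every prescription's `institution_id` has an
#' institution row). A prescription's coverage interval is the closed span
#' `[dispense_date, dispense_date + days_supplied - 1]`.
#'
#' `dispense_date` may be `NA` (a claim whose prescription date is missing in
#' the source); such claims are carried through so the cohort stage can apply
#' its missing-date exclusion rule. All other dates must parse.
#'
#' @param members,enrollment,diagnoses,prescriptions,institutions Data frames
#'   following the schemas in the package data dictionary
#'   (`system.file("extdata", "data_dictionary.md", package = "hypnorx")`).
#' @param validate Run invariant checks (default `TRUE`).
#' @return A `claims_dataset`: a named list of five tibbles.
#' @examples
#' ds <- claims_dataset(
#'   members = data.frame(member_id = "m1", birth_year_month = "1980-04",
#'                        sex = "female"),
#'   enrollment = data.frame(member_id = "m1",
#'                           start_date = as.Date("2017-01-01"),
#'                           end_date = as.Date("2020-03-31")),
#'   diagnoses = data.frame(member_id = "m1",
#'                          claim_date = as.Date("2018-05-10"),
#'                          icd10_code = "G470", setting = "outpatient"),
#'   prescriptions = data.frame(member_id = "m1",
#'                              dispense_date = as.Date("2018-05-10"),
#'                              generic_name = "Brotizolam",
#'                              days_supplied = 30L, bedtime_flag = TRUE,
#'                              prn_flag = FALSE, institution_id = "i1",
#'                              setting = "outpatient"),
#'   institutions = data.frame(institution_id = "i1",
#'                             primary_department = "other", n_beds = 0L)
#' )
#' ds
#' @export
claims_dataset <- function(members, enrollment, diagnoses, prescriptions,
                           institutions, validate = TRUE) {
  tables <- list(members = members, enrollment = enrollment,
                 diagnoses = diagnoses, prescriptions = prescriptions,
                 institutions = institutions)
  tables <- purrr::imap(tables, coerce_table)
  ds <- structure(tables, class = "claims_dataset")
  if (validate) validate_claims(ds)
  ds
}

coerce_table <- function(df, table) {
  schema <- CLAIMS_SCHEMAS[[table]]
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("table '%s' is missing column(s): %s", table,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- tibble::as_tibble(df)[names(schema)]
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      integer   = as.integer(df[[col]]),
      logical   = as.logical(df[[col]]),
      Date      = as.Date(df[[col]])
    )
  }
  df
}

#' Validate a claims dataset against the domain invariants
#'
#' @param ds A `claims_dataset`.
#' @return `ds`, invisibly; aborts with the table, row number and field on the
#'   first violation found in each table.
#' @export
validate_claims <- function(ds) {
  stopifnot(inherits(ds, "claims_dataset"))
  fail <- function(table, row, field, msg) {
    stop(sprintf("claims validation: %s (table '%s', row %d, field '%s')",
                 msg, table, row, field), call. = FALSE)
  }
  check <- function(bad, table, field, msg) {
    if (any(bad)) fail(table, which(bad)[1], field, msg)
  }

  m <- ds$members
  check(is.na(m$member_id) | m$member_id == "", "members", "member_id",
        "missing member_id")
  check(duplicated(m$member_id), "members", "member_id",
        "duplicate member_id")
  check(!grepl("^\\d{4}-(0[1-9]|1[0-2])$", m$birth_year_month),
        "members", "birth_year_month", "not a valid year-month (YYYY-MM)")
  check(!m$sex %in% SEXES, "members", "sex", "unknown sex code")

  e <- ds$enrollment
  check(is.na(e$start_date) | is.na(e$end_date), "enrollment", "start_date",
        "unparseable date")
  check(e$start_date > e$end_date, "enrollment", "end_date",
        "start_date after end_date")

  d <- ds$diagnoses
  check(is.na(d$claim_date), "diagnoses", "claim_date", "unparseable date")
  check(!grepl("^[A-Z][0-9]{2,3}$", d$icd10_code), "diagnoses", "icd10_code",
        "ICD-10 code must be a letter followed by 2-3 digits")
  check(!d$setting %in% SETTINGS, "diagnoses", "setting", "unknown setting")

  p <- ds$prescriptions
  check(is.na(p$days_supplied) | p$days_supplied < 1L, "prescriptions",
        "days_supplied", "days_supplied must be >= 1")
  check(is.na(p$bedtime_flag), "prescriptions", "bedtime_flag",
        "bedtime_flag must be TRUE/FALSE")
  check(is.na(p$prn_flag), "prescriptions", "prn_flag",
        "prn_flag must be TRUE/FALSE")
  check(!p$setting %in% SETTINGS, "prescriptions", "setting",
        "unknown setting")

  i <- ds$institutions
  check(duplicated(i$institution_id), "institutions", "institution_id",
        "duplicate institution_id")
  check(!i$primary_department %in% DEPARTMENTS, "institutions",
        "primary_department", "unknown department")
  check(is.na(i$n_beds) | i$n_beds < 0L, "institutions", "n_beds",
        "n_beds must be >= 0")

  # referential integrity
  for (tab in c("enrollment", "diagnoses", "prescriptions")) {
    check(!ds[[tab]]$member_id %in% m$member_id, tab, "member_id",
          "member_id has no member record")
  }
  check(!p$institution_id %in% i$institution_id, "prescriptions",
        "institution_id", "institution_id has no institution record")
  invisible(ds)
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  for (tab in CLAIMS_TABLES) {
    cat(sprintf("  %-13s %6d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

claims_file_paths <- function(dir) {
  stats::setNames(file.path(dir, paste0(CLAIMS_TABLES, ".csv")),
                  CLAIMS_TABLES)
}

#' Read the five claims tables from delimited files
#'
#' Reads comma- or tab-separated UTF-8 files with a header row, one per
#' table, parses them into typed records and validates the result. Dates are
#' ISO 8601 (`YYYY-MM-DD`); an empty `dispense_date` is read as missing, any
#' other unparseable date is an error naming the file and row.
#'
#' @param paths Either a directory containing `members.csv`,
#'   `enrollment.csv`, `diagnoses.csv`, `prescriptions.csv`,
#'   `institutions.csv`, or a named character vector/list with those five
#'   names giving explicit file paths.
#' @return A validated [claims_dataset()].
#' @export
read_claims_tables <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths))) {
    paths <- claims_file_paths(paths)
  }
  paths <- unlist(paths)
  missing_tabs <- setdiff(CLAIMS_TABLES, names(paths))
  if (length(missing_tabs) > 0) {
    stop("no path given for table(s): ", paste(missing_tabs, collapse = ", "),
         call. = FALSE)
  }
  tables <- purrr::imap(paths[CLAIMS_TABLES], read_one_table)
  do.call(claims_dataset, tables)
}

read_one_table <- function(path, table) {
  if (!file.exists(path)) {
    stop(sprintf("missing file for table '%s': %s", table, path),
         call. = FALSE)
  }
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  schema <- CLAIMS_SCHEMAS[[table]]
  # read everything as text, then parse per schema so that errors can name
  # the file, row and field
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("file %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- raw[names(schema)]
  for (col in names(schema)) {
    if (schema[[col]] == "Date") {
      parsed <- as.Date(out[[col]], format = "%Y-%m-%d")
      bad <- is.na(parsed) & !is.na(out[[col]]) & out[[col]] != ""
      # a blank dispense_date is a genuinely missing prescription date;
      # garbage that fails to parse is a file error
      if (any(bad)) {
        stop(sprintf("file %s, row %d, field '%s': unparseable date '%s'",
                     path, which(bad)[1], col, out[[col]][which(bad)[1]]),
             call. = FALSE)
      }
      if (!(table == "prescriptions" && col == "dispense_date") &&
          anyNA(parsed)) {
        stop(sprintf("file %s, row %d, field '%s': missing date",
                     path, which(is.na(parsed))[1], col), call. = FALSE)
      }
      out[[col]] <- parsed
    } else if (schema[[col]] == "logical") {
      out[[col]] <- toupper(out[[col]]) %in% c("TRUE", "T", "1")
    } else if (schema[[col]] == "integer") {
      out[[col]] <- as.integer(out[[col]])
    }
  }
  out
}

#' Write a claims dataset as five delimited files
#'
#' The inverse of [read_claims_tables()]: writes `members.csv` ...
#' `institutions.csv` under `dir`. Reading the output back yields an
#' identical dataset.
#'
#' @param ds A `claims_dataset`.
#' @param dir Output directory (created if needed).
#' @return The five file paths, invisibly.
#' @export
write_claims_tables <- function(ds, dir) {
  stopifnot(inherits(ds, "claims_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- claims_file_paths(dir)
  for (tab in CLAIMS_TABLES) {
    readr::write_csv(ds[[tab]], paths[[tab]], progress = FALSE)
  }
  invisible(paths)
}

#' Merge enrollment intervals into disjoint continuous spans
#'
#' Collapses each member's closed day-granular enrollment intervals, merging
#' two intervals whenever the uncovered gap between them is at most
#' `max_gap_days`. With the default `max_gap_days = 0`, adjacent intervals
#' (end + 1 = next start) merge and the set of covered days is preserved
#' exactly, which makes "continuous enrollment for >= N months" decidable.
#'
#' @param intervals Data frame with `member_id`, `start_date`, `end_date`
#'   (closed intervals).
#' @param max_gap_days Largest uncovered gap, in days, still treated as
#'   continuous. Default 0: strictly continuous.
#' @return A tibble of disjoint, sorted intervals per member.
#' @examples
#' merge_enrollment(data.frame(
#'   member_id = "m1",
#'   start_date = as.Date(c("2018-01-01", "2018-07-01")),
#'   end_date = as.Date(c("2018-06-30", "2018-12-31"))
#' ))
#' @export
merge_enrollment <- function(intervals, max_gap_days = 0L) {
  stopifnot(max_gap_days >= 0)
  intervals <- tibble::as_tibble(intervals)
  if (nrow(intervals) == 0) {
    return(tibble::tibble(member_id = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character())))
  }
  stopifnot(all(intervals$start_date <= intervals$end_date))
  intervals %>%
    dplyr::arrange(.data$member_id, .data$start_date, .data$end_date) %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::mutate(
      prev_end = dplyr::lag(cummax(as.integer(.data$end_date))),
      run = cumsum(is.na(.data$prev_end) |
                     as.integer(.data$start_date) >
                       .data$prev_end + max_gap_days + 1L)
    ) %>%
    dplyr::group_by(.data$member_id, .data$run) %>%
    dplyr::summarise(start_date = min(.data$start_date),
                     end_date = max(.data$end_date), .groups = "drop") %>%
    dplyr::select("member_id", "start_date", "end_date")
}
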