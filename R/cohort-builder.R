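AGE_GROUPS <- c("20-34", "35-49", "50-64", "65-74")
COMORBIDITIES <- c("substance_use", "schizophrenia_spectrum", "bipolar",
                   "depressive", "anxiety", "neurocognitive",
                   "other_psychiatric")
REASON_CODES <- c("no_insomnia_dx", "no_hypnotic", "age_out_of_range",
                  "insufficient_enrollment", "narcolepsy",
                  "inpatient_at_index", "missing_rx_date",
                  "prn_only_at_index", "multi_prescriber_overlap_at_index",
                  "neither_user_type")

#' Analysis configuration
#'
#' All thresholds of the cohort and tabulation stages in one place; nothing
#' downstream hard-codes a study constant. Defaults encode the study design:
#' a 12-month baseline (washout) window, the 180-day same-MOA threshold for
#' long-term use, eligibility ages 20 to <75, a 30-day episode grace period,
#' strictly continuous enrollment, and Wald 95% intervals.
#'
#' @param study_start,study_end Study window (dates). Defaults
#'   2010-04-01 to 2020-03-31, i.e. fiscal years 2010-2019.
#' @param baseline_months Baseline window length in calendar months ending
#'   the day before the index date.
#' @param long_term_days Minimum pre-index same-MOA continuous coverage for
#'   long-term use, in days.
#' @param age_min_inclusive,age_max_exclusive Eligible age range at index.
#' @param grace_days Episode chaining grace, see [build_episodes()].
#' @param enrollment_max_gap_days Enrollment gap bridged as continuous, see
#'   [merge_enrollment()].
#' @param ci_method `"wald"` or `"wilson"`, see [proportion_ci()].
#' @param seed Integer recorded for provenance (the analysis itself is
#'   deterministic; only simulation consumes seeds).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(study_start = as.Date("2010-04-01"),
                            study_end = as.Date("2020-03-31"),
                            baseline_months = 12L,
                            long_term_days = 180L,
                            age_min_inclusive = 20L,
                            age_max_exclusive = 75L,
                            grace_days = 30L,
                            enrollment_max_gap_days = 0L,
                            ci_method = c("wald", "wilson"),
                            seed = NULL) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start < study_end, long_term_days >= 1,
            baseline_months >= 1, grace_days >= 0,
            enrollment_max_gap_days >= 0,
            age_min_inclusive < age_max_exclusive)
  structure(list(
    study_start = study_start, study_end = study_end,
    baseline_months = as.integer(baseline_months),
    long_term_days = as.integer(long_term_days),
    age_min_inclusive = as.integer(age_min_inclusive),
    age_max_exclusive = as.integer(age_max_exclusive),
    grace_days = as.integer(grace_days),
    enrollment_max_gap_days = as.integer(enrollment_max_gap_days),
    ci_method = match.arg(ci_method),
    seed = seed
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  study window      %s .. %s (FY%d-FY%d)\n", x$study_start,
              x$study_end, fiscal_year_of(x$study_start),
              fiscal_year_of(x$study_end)))
  cat(sprintf("  baseline          %d months\n", x$baseline_months))
  cat(sprintf("  long-term rule    same-MOA episode >= %d days pre-index\n",
              x$long_term_days))
  cat(sprintf("  age at index      [%d, %d)\n", x$age_min_inclusive,
              x$age_max_exclusive))
  cat(sprintf("  grace_days        %d\n", x$grace_days))
  cat(sprintf("  enrollment gap    <= %d days\n", x$enrollment_max_gap_days))
  cat(sprintf("  ci_method         %s\n", x$ci_method))
  invisible(x)
}

#' Japanese fiscal year of a date
#'
#' Analysis periods run April 1 through March 31 and are labeled by the
#' calendar year of their April 1 start, so January-March dates belong to
#' the previous year's label.
#'
#' @param date Date vector.
#' @return Integer fiscal-year labels.
#' @examples
#' fiscal_year_of(as.Date(c("2019-04-01", "2020-03-31")))  # both 2019
#' @export
fiscal_year_of <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m < 4L, y - 1L, y)
}

#' Start and end dates of a fiscal year
#'
#' @param fy Integer fiscal-year label(s).
#' @return A tibble with `fiscal_year`, `fy_start` (April 1), `fy_end`
#'   (March 31 of the following calendar year).
#' @export
fiscal_year_bounds <- function(fy) {
  tibble::tibble(
    fiscal_year = as.integer(fy),
    fy_start = as.Date(sprintf("%d-04-01", fy)),
    fy_end = as.Date(sprintf("%d-03-31", fy + 1L))
  )
}

#' Completed age in years at a date, from a birth year-month
#'
#' Claims carry birth month, not day, so age is computed on year-month
#' arithmetic: completed years from the birth month to the index month
#' (floor; the day of month is ignored).
#'
#' @param birth_year_month `"YYYY-MM"` strings.
#' @param date Index date(s).
#' @return Integer ages.
#' @examples
#' age_at("1975-05", as.Date("2019-04-15"))  # 43: May not yet reached
#' age_at("1975-05", as.Date("2019-05-01"))  # 44
#' @export
age_at <- function(birth_year_month, date) {
  stopifnot(grepl("^\\d{4}-\\d{2}$", birth_year_month))
  by <- as.integer(substr(birth_year_month, 1, 4))
  bm <- as.integer(substr(birth_year_month, 6, 7))
  date <- as.Date(date)
  iy <- as.integer(format(date, "%Y"))
  im <- as.integer(format(date, "%m"))
  months <- (iy - by) * 12L + (im - bm)
  if (any(months < 0)) stop("birth year-month after index date", call. = FALSE)
  months %/% 12L
}

age_group_of <- function(age) {
  cut(age, breaks = c(20, 35, 50, 65, 75), right = FALSE,
      labels = AGE_GROUPS)
}

#' Baseline (washout) window for an index date
#'
#' The window is `[index - baseline_months calendar months, index - 1 day]`,
#' with end-of-month clamping (an index on March 31 and a 1-month baseline
#' start on February 28/29).
#'
#' @param index_date Date vector.
#' @param baseline_months Window length in months.
#' @return Tibble with `baseline_start`, `baseline_end`.
#' @export
baseline_window <- function(index_date, baseline_months = 12L) {
  index_date <- as.Date(index_date)
  tibble::tibble(
    baseline_start = index_date %m-% months(baseline_months),
    baseline_end = index_date - 1L
  )
}

#' @importFrom lubridate %m-%
NULL

# ---- internal engine ------------------------------------------------------

# Pre-resolve everything fiscal-year-independent once per build.
prepare_parts <- function(ds, config, dictionary) {
  rx_all <- ds$prescriptions %>%
    dplyr::mutate(row_ord = dplyr::row_number()) %>%
    dplyr::filter(.data$bedtime_flag, .data$setting == "outpatient")
  missing_members <- unique(
    ds$prescriptions$member_id[is.na(ds$prescriptions$dispense_date)])
  rx <- rx_all %>% dplyr::filter(!is.na(.data$dispense_date))
  rx <- if (nrow(rx) > 0) {
    classify_claims(rx, dictionary) %>%
      dplyr::mutate(cov_end = .data$dispense_date + .data$days_supplied - 1L)
  } else {
    dplyr::mutate(rx, moa_class = character(0), duration_type = character(0),
                  max_days_per_rx = integer(0),
                  cov_end = as.Date(character(0)))
  }
  list(
    rx = rx,
    episodes = build_episodes(
      rx[c("member_id", "dispense_date", "generic_name", "days_supplied")],
      dictionary, config$grace_days),
    enrollment = merge_enrollment(ds$enrollment,
                                  config$enrollment_max_gap_days),
    dx = ds$diagnoses,
    members = ds$members,
    institutions = ds$institutions,
    prescriptions = ds$prescriptions,
    missing_members = missing_members
  )
}

# Decisions and covariates for every member with an index date in one
# fiscal year. Returns a tibble with gate/exclusion reasons, user type and
# resolved covariates.
fy_decisions <- function(parts, fy, config) {
  b <- fiscal_year_bounds(fy)
  period_start <- max(b$fy_start, config$study_start)
  period_end <- min(b$fy_end, config$study_end)

  rx_period <- parts$rx %>%
    dplyr::filter(.data$dispense_date >= period_start,
                  .data$dispense_date <= period_end)
  if (nrow(rx_period) == 0) return(empty_fy_decisions(fy))
  idx <- rx_period %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(index_date = min(.data$dispense_date),
                     .groups = "drop")

  idx <- idx %>%
    dplyr::left_join(parts$members, by = "member_id") %>%
    dplyr::mutate(
      fiscal_year = as.integer(fy),
      age_at_index = age_at(.data$birth_year_month, .data$index_date),
      baseline_start = .data$index_date %m-% months(config$baseline_months),
      baseline_end = .data$index_date - 1L
    )

  member_in <- function(ids) idx$member_id %in% ids

  # --- gates, in rule order ---
  dx_g470 <- parts$dx %>%
    dplyr::filter(.data$setting == "outpatient",
                  startsWith(.data$icd10_code, "G470"))
  g470 <- if (nrow(dx_g470) > 0) {
    dx_g470 %>%
      dplyr::group_by(.data$member_id) %>%
      dplyr::summarise(first_g470 = min(.data$claim_date),
                       .groups = "drop")
  } else {
    tibble::tibble(member_id = character(),
                   first_g470 = as.Date(character()))
  }
  idx <- idx %>% dplyr::left_join(g470, by = "member_id")
  gate_dx <- is.na(idx$first_g470) | idx$first_g470 > idx$index_date

  gate_age <- idx$age_at_index < config$age_min_inclusive |
    idx$age_at_index >= config$age_max_exclusive

  enrolled <- idx %>%
    dplyr::select("member_id", "baseline_start", "baseline_end") %>%
    dplyr::inner_join(parts$enrollment, by = "member_id",
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$start_date <= .data$baseline_start,
                  .data$end_date >= .data$baseline_end) %>%
    dplyr::distinct(.data$member_id)
  gate_enrol <- !member_in(enrolled$member_id)

  # --- exclusions ---
  narco <- parts$dx %>%
    dplyr::filter(startsWith(.data$icd10_code, "G474"),
                  .data$claim_date >= config$study_start,
                  .data$claim_date <= config$study_end)
  excl_narco <- member_in(narco$member_id)

  inp <- dplyr::bind_rows(
    parts$dx %>% dplyr::filter(.data$setting == "inpatient") %>%
      dplyr::select("member_id", date = "claim_date"),
    parts$prescriptions %>%
      dplyr::filter(.data$setting == "inpatient",
                    !is.na(.data$dispense_date)) %>%
      dplyr::select("member_id", date = "dispense_date")
  ) %>%
    dplyr::inner_join(idx[c("member_id", "index_date")], by = "member_id") %>%
    dplyr::filter(.data$date == .data$index_date)
  excl_inpatient <- member_in(inp$member_id)

  excl_missing <- member_in(parts$missing_members)

  rx_m <- parts$rx %>%
    dplyr::inner_join(
      idx[c("member_id", "index_date", "baseline_start", "baseline_end")],
      by = "member_id")
  index_claims <- rx_m %>%
    dplyr::filter(.data$dispense_date == .data$index_date)

  prn <- index_claims %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(prn_only = all(.data$prn_flag), .groups = "drop")
  excl_prn <- member_in(prn$member_id[prn$prn_only])

  multi <- rx_m %>%
    dplyr::filter(.data$dispense_date <= .data$index_date,
                  .data$cov_end >= .data$index_date) %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(n_inst = dplyr::n_distinct(.data$institution_id),
                     .groups = "drop")
  excl_multi <- member_in(multi$member_id[multi$n_inst >= 2])

  # --- user type ---
  baseline_rx <- rx_m %>%
    dplyr::filter(.data$dispense_date >= .data$baseline_start,
                  .data$dispense_date <= .data$baseline_end)
  is_new <- !member_in(baseline_rx$member_id)

  lt <- parts$episodes %>%
    dplyr::inner_join(idx[c("member_id", "index_date")], by = "member_id",
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$start_date <= .data$index_date - config$long_term_days,
                  .data$end_date >= .data$index_date)
  is_lt <- member_in(lt$member_id)

  user_type <- dplyr::case_when(is_new ~ "new",
                                is_lt ~ "long_term",
                                TRUE ~ "neither")

  reasons <- purrr::pmap(
    list(gate_dx, gate_age, gate_enrol, excl_narco, excl_inpatient,
         excl_missing, excl_prn, excl_multi, user_type),
    function(dx, age, enrol, narco, inpat, miss, prn1, multi1, ut) {
      gates <- c("no_insomnia_dx"[dx], "age_out_of_range"[age],
                 "insufficient_enrollment"[enrol])
      if (length(gates) > 0) return(gates)
      excl <- c("narcolepsy"[narco], "inpatient_at_index"[inpat],
                "missing_rx_date"[miss], "prn_only_at_index"[prn1],
                "multi_prescriber_overlap_at_index"[multi1])
      if (length(excl) > 0) return(excl)
      if (ut == "neither") return("neither_user_type")
      character(0)
    })

  idx$reason_codes <- vapply(reasons, paste, character(1), collapse = "|")
  idx$user_type <- ifelse(idx$reason_codes == "", user_type, NA_character_)
  idx$status <- dplyr::case_when(
    idx$reason_codes != "" ~ "excluded",
    user_type == "new" ~ "included_new",
    TRUE ~ "included_long_term")

  covars <- index_covariates(index_claims, idx, parts)
  idx %>%
    dplyr::select("member_id", "fiscal_year", "index_date", "status",
                  "reason_codes", "user_type", "age_at_index", "sex",
                  "baseline_start", "baseline_end") %>%
    dplyr::left_join(covars, by = "member_id")
}

empty_fy_decisions <- function(fy) {
  tibble::tibble(member_id = character(), fiscal_year = integer(),
                 index_date = as.Date(character()), status = character(),
                 reason_codes = character(), user_type = character(),
                 age_at_index = integer(), sex = character(),
                 baseline_start = as.Date(character()),
                 baseline_end = as.Date(character()),
                 index_moa_kind = character(),
                 index_moa_category = character(),
                 n_hypnotics_at_index = integer(),
                 bzd_duration_category = character(),
                 specialty = character(), setting = character())
}

# Index-day covariates: MOA category, hypnotic count, BZD duration type,
# prescriber specialty and clinical setting.
index_covariates <- function(index_claims, idx, parts) {
  if (nrow(index_claims) == 0) {
    return(tibble::tibble(member_id = character(),
                          index_moa_kind = character(),
                          index_moa_category = character(),
                          n_hypnotics_at_index = integer(),
                          bzd_duration_category = character(),
                          specialty = character(), setting = character()))
  }
  moa <- index_claims %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(
      index_moa_category = moa_combo_label(.data$moa_class),
      index_moa_kind = ifelse(dplyr::n_distinct(.data$moa_class) > 1,
                              "multiple", "single"),
      n_hypnotics_at_index =
        dplyr::n_distinct(tolower(.data$generic_name)),
      bzd_duration_category = bzd_duration_value(
        .data$duration_type[.data$moa_class == "BZD"]),
      .groups = "drop")
  # specialty/setting resolve from the index-day claim earliest in record
  # order (ties across institutions broken deterministically)
  inst <- index_claims %>%
    dplyr::arrange(.data$row_ord) %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup() %>%
    dplyr::select("member_id", "institution_id") %>%
    dplyr::left_join(parts$institutions, by = "institution_id") %>%
    dplyr::mutate(
      specialty = dplyr::case_when(
        .data$primary_department == "psychiatry" ~ "psychiatry",
        .data$n_beds <= 19L ~ "GP",
        TRUE ~ "others"),
      setting = ifelse(.data$n_beds <= 19L, "clinic", "hospital")) %>%
    dplyr::select("member_id", "specialty", "setting")
  cm <- comorbidity_flags(
    parts$dx,
    idx[c("member_id", "baseline_start", "baseline_end")])
  moa %>%
    dplyr::left_join(inst, by = "member_id") %>%
    dplyr::left_join(cm, by = "member_id")
}

#' Apply the study's eligibility gates for one member-year
#'
#' Checks, in order: an index date exists in the fiscal year; at least one
#' outpatient insomnia (G470) diagnosis on or before the index date; age at
#' index inside the eligible range; enrollment covering the full baseline
#' window ending the day before the index date. Failures accumulate reason
#' codes; exclusions ([apply_exclusions()]) are a separate, later step.
#'
#' @param member_id One member id.
#' @param fiscal_year Fiscal-year label.
#' @param dataset A [claims_dataset()].
#' @param config An [analysis_config()].
#' @param dictionary Drug dictionary.
#' @return A list with `member_id`, `fiscal_year`, `index_date`, `status`
#'   (`"passed"` or `"excluded"`), and `reason_codes` (character vector,
#'   empty when all gates pass).
#' @export
check_eligibility <- function(member_id, fiscal_year, dataset, config,
                              dictionary = hypnotic_formulary()) {
  parts <- prepare_parts(dataset, config, dictionary)
  d <- fy_decisions(parts, fiscal_year, config)
  row <- d[d$member_id == member_id, ]
  if (nrow(row) == 0) {
    return(list(member_id = member_id, fiscal_year = fiscal_year,
                index_date = as.Date(NA), status = "excluded",
                reason_codes = "no_hypnotic"))
  }
  gate_codes <- intersect(
    strsplit(row$reason_codes, "|", fixed = TRUE)[[1]],
    c("no_insomnia_dx", "age_out_of_range", "insufficient_enrollment"))
  list(member_id = member_id, fiscal_year = fiscal_year,
       index_date = row$index_date,
       status = if (length(gate_codes) > 0) "excluded" else "passed",
       reason_codes = gate_codes)
}

#' Apply the study's exclusion rules for one member at an index date
#'
#' The five exclusions: a narcolepsy/cataplexy (G474) diagnosis anywhere in
#' the study window; hospitalization (any inpatient claim) on the index
#' date; any hypnotic prescription claim with a missing dispense date;
#' only as-needed (PRN) hypnotics on the index date; and overlapping
#' hypnotic coverage from two or more prescribing institutions at the index
#' date.
#'
#' @inheritParams check_eligibility
#' @param index_date The member's index date.
#' @return Character vector of exclusion reason codes (empty = not
#'   excluded).
#' @export
apply_exclusions <- function(member_id, index_date, dataset, config,
                             dictionary = hypnotic_formulary()) {
  parts <- prepare_parts(dataset, config, dictionary)
  d <- fy_decisions(parts, fiscal_year_of(index_date), config)
  row <- d[d$member_id == member_id, ]
  stopifnot(nrow(row) == 1, row$index_date == as.Date(index_date))
  intersect(strsplit(row$reason_codes, "|", fixed = TRUE)[[1]],
            c("narcolepsy", "inpatient_at_index", "missing_rx_date",
              "prn_only_at_index", "multi_prescriber_overlap_at_index"))
}

#' Classify a member-year as a new, long-term, or neither user
#'
#' New: no bedtime outpatient hypnotic dispense date inside the baseline
#' window (the `baseline_months`-month window ending the day before the
#' index date). Long-term: not new, and some MOA class has a coverage
#' episode containing the index date that started at least `long_term_days`
#' before it (episode start on or before index - `long_term_days`).
#' Otherwise neither — such member-years stay in the audit log but in no
#' analysis cohort. The two definitions are disjoint by construction: new
#' requires an empty baseline, long-term a covered one.
#'
#' @inheritParams apply_exclusions
#' @param episodes Episodes from [build_episodes()] for the same dataset
#'   and grace setting.
#' @return `"new"`, `"long_term"`, or `"neither"`.
#' @export
classify_user <- function(member_id, index_date, episodes, dataset, config) {
  index_date <- as.Date(index_date)
  bw <- baseline_window(index_date, config$baseline_months)
  rx <- dataset$prescriptions %>%
    dplyr::filter(.data$member_id == !!member_id, .data$bedtime_flag,
                  .data$setting == "outpatient", !is.na(.data$dispense_date))
  in_baseline <- rx$dispense_date >= bw$baseline_start &
    rx$dispense_date <= bw$baseline_end
  if (!any(in_baseline)) return("new")
  ep <- episodes %>%
    dplyr::filter(.data$member_id == !!member_id,
                  .data$start_date <= index_date - config$long_term_days,
                  .data$end_date >= index_date)
  if (nrow(ep) > 0) "long_term" else "neither"
}

#' Build the per-fiscal-year cohorts of new and long-term hypnotic users
#'
#' One pass per fiscal year in the study window. Every member whose first
#' bedtime outpatient hypnotic claim of the year defines an index date
#' receives exactly one eligibility decision; members passing all gates and
#' exclusions and classifying as new or long-term users enter the cohort
#' with covariates resolved at the index date (age, sex, index MOA
#' category, hypnotic count, BZD duration type, prescriber specialty,
#' clinical setting, baseline psychiatric comorbidity flags). The run is
#' fully deterministic: identical inputs give identical output.
#'
#' @param dataset A validated [claims_dataset()].
#' @param config An [analysis_config()].
#' @param dictionary Drug dictionary.
#' @return A list of class `cohort_result`: `cohort` (one row per included
#'   member-year) and `audit` (one eligibility decision per member-year
#'   with an index date; reason codes pipe-joined).
#' @export
build_cohort <- function(dataset, config = analysis_config(),
                         dictionary = hypnotic_formulary()) {
  stopifnot(inherits(dataset, "claims_dataset"),
            inherits(config, "analysis_config"))
  parts <- prepare_parts(dataset, config, dictionary)
  fys <- seq(fiscal_year_of(config$study_start),
             fiscal_year_of(config$study_end))
  decisions <- purrr::map(fys, ~fy_decisions(parts, .x, config)) %>%
    dplyr::bind_rows()
  audit <- decisions %>%
    dplyr::select("member_id", "fiscal_year", "index_date", "status",
                  "reason_codes")
  cohort <- decisions %>%
    dplyr::filter(.data$status != "excluded") %>%
    dplyr::mutate(age_group = as.character(age_group_of(.data$age_at_index)),
                  n_hypnotics_bucket =
                    bucket_n_hypnotics(.data$n_hypnotics_at_index)) %>%
    dplyr::select("member_id", "fiscal_year", "user_type", "index_date",
                  "age_at_index", "age_group", "sex", "index_moa_kind",
                  "index_moa_category", "n_hypnotics_at_index",
                  "n_hypnotics_bucket", "bzd_duration_category",
                  "specialty", "setting",
                  dplyr::starts_with("cm_"))
  structure(list(cohort = cohort, audit = audit, config = config),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result>\n")
  cat(sprintf("  member-years with an index date: %d\n", nrow(x$audit)))
  cat(sprintf("  included: %d new, %d long-term\n",
              sum(x$cohort$user_type == "new"),
              sum(x$cohort$user_type == "long_term")))
  cat(sprintf("  excluded member-years: %d\n",
              sum(x$audit$status == "excluded")))
  invisible(x)
}
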