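TREND_CATEGORIES <- c("BZD", "Z_DRUG", "MRA", "ORA", "OTHER", "multiple")
BZD_DURATION_CATEGORIES <- c("long", "intermediate", "short", "ultrashort",
                             "two_or_more_types")
N_HYPNOTIC_BUCKETS <- c("1", "2", "3", "4+")

# canonical combination label: classes in fixed taxonomy order, "+"-joined
moa_combo_label <- function(classes) {
  paste(MOA_CLASSES[MOA_CLASSES %in% classes], collapse = "+")
}

bzd_duration_value <- function(duration_types) {
  u <- unique(duration_types)
  if (length(u) == 0) return(NA_character_)
  if (length(u) == 1) u else "two_or_more_types"
}

bucket_n_hypnotics <- function(n) {
  ifelse(n >= 4L, "4+", as.character(n))
}

#' MOA category of a member's index-day prescriptions
#'
#' The distinct mechanism-of-action classes among all (bedtime hypnotic)
#' claims dispensed on the index date. All generics of one class count as a
#' single MOA — two different benzodiazepines are still "single BZD" — so
#' `kind` is `"multiple"` only when two or more *classes* co-occur. The
#' combination label lists classes in the fixed order BZD, Z_DRUG, MRA,
#' ORA, OTHER joined by `"+"`.
#'
#' @param claims Index-day prescription claims (needs `generic_name`).
#' @param dictionary Drug dictionary.
#' @return A list with `kind` (`"single"`/`"multiple"`), `classes`
#'   (character vector) and `combo_label`.
#' @examples
#' moa_category_at_index(
#'   tibble::tibble(generic_name = c("Brotizolam", "Zolpidem tartrate")))
#' @export
moa_category_at_index <- function(claims, dictionary = hypnotic_formulary()) {
  stopifnot(nrow(claims) >= 1)
  cls <- classify_claims(claims, dictionary)$moa_class
  classes <- MOA_CLASSES[MOA_CLASSES %in% cls]
  list(kind = if (length(classes) > 1) "multiple" else "single",
       classes = classes,
       combo_label = paste(classes, collapse = "+"))
}

#' Number of distinct hypnotics at the index date
#'
#' Distinct generic names (case-insensitive) among index-day claims; the
#' same generic dispensed by two institutions counts once. Reported in the
#' buckets 1 / 2 / 3 / 4+.
#'
#' @param claims Index-day prescription claims.
#' @return A list with `n` (integer) and `bucket`.
#' @export
n_hypnotics_at_index <- function(claims) {
  stopifnot(nrow(claims) >= 1)
  n <- dplyr::n_distinct(tolower(claims$generic_name))
  list(n = n, bucket = bucket_n_hypnotics(n))
}

#' BZD action-duration category at the index date
#'
#' For members whose index category includes a benzodiazepine: the shared
#' duration type (long / intermediate / short / ultrashort) when all
#' index-day BZDs agree, else `"two_or_more_types"`.
#'
#' @param claims Index-day prescription claims (at least one BZD).
#' @param dictionary Drug dictionary.
#' @return One of the duration categories.
#' @export
bzd_duration_category <- function(claims, dictionary = hypnotic_formulary()) {
  cl <- classify_claims(claims, dictionary)
  val <- bzd_duration_value(cl$duration_type[cl$moa_class == "BZD"])
  if (is.na(val)) stop("no BZD among the index-day claims", call. = FALSE)
  val
}

#' Baseline psychiatric comorbidity flags
#'
#' Flags seven non-exclusive comorbidity categories from diagnosis claims in
#' each member's baseline window, by ICD-10 category prefix:
#' substance use disorders (F10-F19), schizophrenia spectrum disorders
#' (F20-F29), bipolar disorders (F30, F31), depressive disorders (F32, F33),
#' anxiety disorders (F40-F42), neurocognitive disorders (restricted to
#' Alzheimer's disease: F00 and G30 only — other dementias such as F03 fall
#' in the residual), and other psychiatric comorbidities (any F00-F99 code
#' not captured by the six named sets).
#'
#' @param diagnoses Diagnosis claims table.
#' @param windows Tibble with `member_id`, `baseline_start`, `baseline_end`
#'   (one row per member-year; see [baseline_window()]).
#' @return A tibble with `member_id` and logical columns `cm_substance_use`,
#'   `cm_schizophrenia_spectrum`, `cm_bipolar`, `cm_depressive`,
#'   `cm_anxiety`, `cm_neurocognitive`, `cm_other_psychiatric`; every
#'   member in `windows` appears, unflagged members all-`FALSE`.
#' @export
comorbidity_flags <- function(diagnoses, windows) {
  cat3 <- substr(diagnoses$icd10_code, 1, 3)
  named <- tibble::tibble(
    member_id = diagnoses$member_id,
    claim_date = diagnoses$claim_date,
    cm_substance_use = cat3 %in% sprintf("F1%d", 0:9),
    cm_schizophrenia_spectrum = cat3 %in% sprintf("F2%d", 0:9),
    cm_bipolar = cat3 %in% c("F30", "F31"),
    cm_depressive = cat3 %in% c("F32", "F33"),
    cm_anxiety = cat3 %in% c("F40", "F41", "F42"),
    cm_neurocognitive = cat3 %in% c("F00", "G30")
  )
  captured <- named$cm_substance_use | named$cm_schizophrenia_spectrum |
    named$cm_bipolar | named$cm_depressive | named$cm_anxiety |
    cat3 == "F00"
  named$cm_other_psychiatric <- startsWith(cat3, "F") & !captured
  flag_cols <- paste0("cm_", COMORBIDITIES)
  flags <- windows %>%
    dplyr::inner_join(named, by = "member_id",
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$claim_date >= .data$baseline_start,
                  .data$claim_date <= .data$baseline_end) %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(flag_cols), any),
                     .groups = "drop")
  windows %>%
    dplyr::distinct(.data$member_id) %>%
    dplyr::left_join(flags, by = "member_id") %>%
    dplyr::mutate(dplyr::across(dplyr::all_of(flag_cols),
                                ~dplyr::coalesce(.x, FALSE)))
}

#' Proportion with a two-sided 95% confidence interval
#'
#' Point estimate `100 * count / denominator` with a two-sided interval on
#' the percent scale. `"wald"` (the default) is the normal approximation
#' `p +/- z * sqrt(p(1-p)/n)`, clipped to `[0, 100]`; `"wilson"` is the
#' score interval, preferable at small n or extreme proportions (its lower
#' bound is positive at count 0 sample sizes where Wald degenerates). At
#' the cohort sizes this package targets (tens of thousands) the two are
#' numerically indistinguishable at display precision.
#'
#' Estimates are returned unrounded; display rounding is one decimal, half
#' away from zero ([format_pct()]).
#'
#' @param count,denominator Integer vectors (recycled), `0 <= count <=
#'   denominator`, `denominator >= 1`.
#' @param method `"wald"` or `"wilson"`.
#' @param conf_level Coverage, default 0.95.
#' @return A tibble with `count`, `denominator`, `pct`, `ci_low`,
#'   `ci_high` (percent scale).
#' @examples
#' proportion_ci(29892, 55263)  # 54.1% [53.7, 54.5]
#' @export
proportion_ci <- function(count, denominator, method = c("wald", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(all(denominator >= 1), all(count >= 0),
            all(count <= denominator))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- count / denominator
  n <- denominator
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    lo <- center - half
    hi <- center + half
  }
  tibble::tibble(
    count = count, denominator = denominator,
    pct = 100 * p,
    ci_low = 100 * pmax(lo, 0),
    ci_high = 100 * pmin(hi, 1)
  )
}

#' Round and format percentages for display
#'
#' One decimal, half away from zero (so 0.05 -> 0.1), matching the
#' reporting convention of descriptive claims tabulations. Rounding is a
#' display concern only: every internal sum and partition check runs on
#' unrounded counts.
#'
#' @param x Numeric percent values.
#' @param digits Decimal places.
#' @return Numeric, rounded.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' @rdname round_half_away
#' @export
format_pct <- function(x, digits = 1) {
  sprintf(paste0("%.", digits, "f"), round_half_away(x, digits))
}

# top-level analysis category: the single class, or "multiple"
trend_category <- function(kind, combo_label) {
  ifelse(kind == "multiple", "multiple", combo_label)
}

as_cohort_tibble <- function(cohort) {
  if (inherits(cohort, "cohort_result")) cohort$cohort else cohort
}

count_with_ci <- function(df, group_cols, category_col, categories,
                          ci_method, groups = NULL) {
  if (is.null(groups)) {
    groups <- dplyr::distinct(df,
                              dplyr::across(dplyr::all_of(group_cols)))
  }
  cat_tbl <- tibble::tibble(factor(categories, levels = categories))
  names(cat_tbl) <- category_col
  raw <- df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols,
                                                  category_col)))) %>%
    dplyr::summarise(count = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(!!category_col := factor(
      as.character(.data[[category_col]]), levels = categories))
  counts <- tidyr::crossing(groups, cat_tbl) %>%
    dplyr::left_join(raw, by = c(group_cols, category_col)) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) %>%
    dplyr::mutate(denominator = sum(.data$count)) %>%
    dplyr::ungroup() %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(c(group_cols,
                                                 category_col))))
  ci <- proportion_ci(counts$count, pmax(counts$denominator, 1L),
                      method = ci_method)
  counts$pct <- ifelse(counts$denominator == 0, NA_real_, ci$pct)
  counts$ci_low <- ifelse(counts$denominator == 0, NA_real_, ci$ci_low)
  counts$ci_high <- ifelse(counts$denominator == 0, NA_real_, ci$ci_high)
  counts
}

#' Yearly MOA-class trend table
#'
#' For one user type, per fiscal year (and per stratum when `by` is given):
#' the distribution of the index MOA category over `BZD`, `Z_DRUG`, `MRA`,
#' `ORA`, `OTHER` and `multiple` (two or more classes at index), each as a
#' count and proportion of that year's cohort with its confidence interval.
#' Category counts always partition the denominator exactly. A year-stratum
#' with no members is emitted with denominator 0 and `NA` estimates rather
#' than dropped.
#'
#' @param cohort A [build_cohort()] result or its `cohort` tibble.
#' @param user_type `"new"` or `"long_term"`.
#' @param by Optional character vector of cohort columns to stratify by
#'   (e.g. `"sex"`, `"age_group"`, `"specialty"`, a `cm_*` flag).
#' @param fiscal_years Optional vector of fiscal years to force into the
#'   table; years with no cohort members are emitted with denominator 0 and
#'   `NA` estimates. Default: the years observed in the cohort.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return A tidy tibble: one row per fiscal year (x stratum) x category.
#' @export
trend_by_year <- function(cohort, user_type = c("new", "long_term"),
                          by = NULL, fiscal_years = NULL,
                          ci_method = c("wald", "wilson")) {
  user_type <- match.arg(user_type)
  ci_method <- match.arg(ci_method)
  df <- as_cohort_tibble(cohort) %>%
    dplyr::filter(.data$user_type == !!user_type) %>%
    dplyr::mutate(category = trend_category(.data$index_moa_kind,
                                            .data$index_moa_category))
  groups <- NULL
  if (!is.null(fiscal_years)) {
    groups <- tibble::tibble(fiscal_year = as.integer(sort(fiscal_years)))
    if (!is.null(by)) {
      groups <- tidyr::crossing(
        groups, dplyr::distinct(df, dplyr::across(dplyr::all_of(by))))
    }
  }
  count_with_ci(df, c("fiscal_year", by), "category", TREND_CATEGORIES,
                ci_method, groups = groups)
}

#' Pooled-window prescription pattern tables
#'
#' Distribution of index prescriptions over a pooled window of fiscal years
#' (the study pools its final two years). The unit is the patient-year: a
#' member indexed in two pooled years contributes twice. Three nested
#' tables are produced:
#'
#' * `moa` — the top-level MOA-category distribution (same categories as
#'   [trend_by_year()]), denominator = all member-years of the user type in
#'   the window;
#' * `bzd_duration` — action-duration types among members prescribed a BZD
#'   at index (denominator = member-years whose index category includes
#'   BZD, whether alone or in combination);
#' * `multi_combo` — MOA-class combinations among multiple-MOA
#'   member-years (denominator = member-years with `kind == "multiple"`).
#'
#' @inheritParams trend_by_year
#' @param fiscal_years Fiscal years pooled into the window (default the two
#'   most recent in the cohort).
#' @param by Optional segmentation columns, e.g.
#'   `c("cm_depressive", "age_group")` for a comorbidity-by-age breakdown.
#' @return A named list of three tidy tibbles.
#' @export
pattern_distribution <- function(cohort, user_type = c("new", "long_term"),
                                 fiscal_years = NULL, by = NULL,
                                 ci_method = c("wald", "wilson")) {
  user_type <- match.arg(user_type)
  ci_method <- match.arg(ci_method)
  df <- as_cohort_tibble(cohort) %>%
    dplyr::filter(.data$user_type == !!user_type)
  if (is.null(fiscal_years)) {
    fiscal_years <- utils::tail(sort(unique(df$fiscal_year)), 2)
  }
  stopifnot(length(fiscal_years) >= 1)
  df <- df %>%
    dplyr::filter(.data$fiscal_year %in% fiscal_years) %>%
    dplyr::mutate(window = paste(range(fiscal_years), collapse = "-"),
                  category = trend_category(.data$index_moa_kind,
                                            .data$index_moa_category))
  group_cols <- c("window", by)

  bzd <- df %>%
    dplyr::filter(!is.na(.data$bzd_duration_category))
  multi <- df %>% dplyr::filter(.data$index_moa_kind == "multiple")
  combos <- sort(unique(multi$index_moa_category))

  list(
    moa = count_with_ci(df, group_cols, "category", TREND_CATEGORIES,
                        ci_method),
    bzd_duration = count_with_ci(bzd, group_cols, "bzd_duration_category",
                                 BZD_DURATION_CATEGORIES, ci_method),
    multi_combo = if (nrow(multi) > 0) {
      count_with_ci(multi, group_cols, "index_moa_category", combos,
                    ci_method)
    } else {
      tibble::tibble(window = character(), index_moa_category = factor(),
                     count = integer(), denominator = integer(),
                     pct = numeric(), ci_low = numeric(),
                     ci_high = numeric())
    }
  )
}
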