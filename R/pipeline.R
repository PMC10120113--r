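#' Write a generated scenario to disk
#'
#' Runs the synthetic generator and writes the five claims tables, the
#' ground-truth table, the scenario (YAML, for provenance) and a run
#' manifest into `out_dir`. Identical scenarios (including the seed)
#' produce byte-identical data files.
#'
#' @param scenario A [scenario_config()], or the path of a YAML file
#'   readable by [read_scenario()].
#' @param out_dir Output directory.
#' @return The [simulate_claims()] result, invisibly.
#' @export
simulate_scenario <- function(scenario, out_dir) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  sim <- simulate_claims(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_claims_tables(sim$dataset, out_dir)
  readr::write_csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   progress = FALSE)
  yaml::write_yaml(scenario_to_list(scenario),
                   file.path(out_dir, "scenario.yaml"))
  write_manifest(out_dir, stage = "simulate",
                 config = scenario_to_list(scenario),
                 files = c(paste0(CLAIMS_TABLES, ".csv"),
                           "ground_truth.csv"))
  invisible(sim)
}

scenario_to_list <- function(sc) {
  out <- unclass(sc)
  out$comorbidity_prevalence <- lapply(out$comorbidity_prevalence, as.list)
  out$age_distribution <- as.list(out$age_distribution)
  out$archetype_mix <- as.list(out$archetype_mix)
  out$moa_mix_new <- as.list(out$moa_mix_new)
  out$moa_mix_longterm <- as.list(out$moa_mix_longterm)
  out
}

#' Read a scenario file
#'
#' @param path YAML file with [scenario_config()] fields; omitted fields
#'   take the defaults.
#' @return A `scenario_config`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  unlist_named <- function(x) if (is.list(x)) unlist(x) else x
  for (f in c("age_distribution", "archetype_mix", "moa_mix_new",
              "moa_mix_longterm")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist_named(raw[[f]])
  }
  if (!is.null(raw$comorbidity_prevalence)) {
    raw$comorbidity_prevalence <- lapply(raw$comorbidity_prevalence,
                                         unlist_named)
  }
  do.call(scenario_config, raw)
}

#' Read an analysis configuration file
#'
#' @param path YAML file with [analysis_config()] fields; omitted fields
#'   take the defaults.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

#' Run the full study pipeline
#'
#' Validate, build episodes, build the per-fiscal-year cohorts, and produce
#' the trend and pattern tabulations for both user types. When `out_dir` is
#' given, all intermediates and results are written as tidy delimited
#' tables (episodes, audit log, cohort, trend and pattern tables), plus a
#' human-readable report with the patient-flow counts and a run manifest
#' echoing every configuration value actually used. Reruns on identical
#' inputs are bit-identical.
#'
#' @param dataset A [claims_dataset()] or a directory to read one from.
#' @param config An [analysis_config()] or the path of a YAML config file.
#' @param out_dir Optional output directory.
#' @param pattern_years Fiscal years pooled for the pattern analysis;
#'   default the two most recent study years.
#' @param dictionary Drug dictionary.
#' @return A list of class `study_result`: `cohort_result`, `episodes`,
#'   `trend` (per user type), `patterns` (per user type), `flow` (the
#'   patient-flow count block), `config`.
#' @export
run_study <- function(dataset, config = analysis_config(), out_dir = NULL,
                      pattern_years = NULL,
                      dictionary = hypnotic_formulary()) {
  if (is.character(dataset)) dataset <- read_claims_tables(dataset)
  if (is.character(config)) config <- read_analysis_config(config)
  validate_claims(dataset)

  rx <- dataset$prescriptions %>%
    dplyr::filter(.data$bedtime_flag, .data$setting == "outpatient",
                  !is.na(.data$dispense_date))
  episodes <- build_episodes(
    rx[c("member_id", "dispense_date", "generic_name", "days_supplied")],
    dictionary, config$grace_days)
  res <- build_cohort(dataset, config, dictionary)
  fys <- sort(unique(res$audit$fiscal_year))
  if (is.null(pattern_years)) pattern_years <- utils::tail(fys, 2)

  trend <- list(
    new = trend_by_year(res, "new", fiscal_years = fys,
                        ci_method = config$ci_method),
    long_term = trend_by_year(res, "long_term", fiscal_years = fys,
                              ci_method = config$ci_method))
  patterns <- list(
    new = pattern_distribution(res, "new", fiscal_years = pattern_years,
                               ci_method = config$ci_method),
    long_term = pattern_distribution(res, "long_term",
                                     fiscal_years = pattern_years,
                                     ci_method = config$ci_method))
  flow <- flow_counts(res)
  out <- structure(list(cohort_result = res, episodes = episodes,
                        trend = trend, patterns = patterns, flow = flow,
                        config = config),
                   class = "study_result")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

# Patient-flow block: index member-years, exclusions by reason, included
# new / long-term, and the residual "neither" group — the conservation
# identity cohort + exclusions = member-years with an index date.
flow_counts <- function(res) {
  audit <- res$audit
  reasons <- audit %>%
    dplyr::filter(.data$status == "excluded") %>%
    dplyr::mutate(first_reason = vapply(
      strsplit(.data$reason_codes, "|", fixed = TRUE),
      function(x) x[1], character(1))) %>%
    dplyr::count(.data$first_reason, name = "n")
  tibble::tibble(
    stage = c("member_years_with_index", "included_new",
              "included_long_term",
              paste0("excluded_", reasons$first_reason)),
    n = c(nrow(audit), sum(audit$status == "included_new"),
          sum(audit$status == "included_long_term"), reasons$n)
  )
}

write_study_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
  }
  w(out$episodes, "episodes.csv")
  w(out$cohort_result$audit, "audit_log.csv")
  w(out$cohort_result$cohort, "cohort.csv")
  w(out$trend$new, "trend_new_users.csv")
  w(out$trend$long_term, "trend_long_term_users.csv")
  for (ut in c("new", "long_term")) {
    for (tab in names(out$patterns[[ut]])) {
      w(out$patterns[[ut]][[tab]],
        sprintf("pattern_%s_%s.csv", ut, tab))
    }
  }
  writeLines(render_report(out), file.path(out_dir, "report.txt"))
  write_manifest(out_dir, stage = "run",
                 config = unclass_config(out$config),
                 files = setdiff(list.files(out_dir),
                                 c("manifest.json", "report.txt")))
  invisible(out_dir)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$study_start <- as.character(out$study_start)
  out$study_end <- as.character(out$study_end)
  out
}

render_report <- function(out) {
  res <- out$cohort_result
  lines <- c(
    "Hypnotic prescribing study report",
    "=================================",
    "",
    "Patient flow (member-years):",
    sprintf("  %-45s %8d", out$flow$stage, out$flow$n),
    "",
    "Configuration:",
    sprintf("  %-24s %s", names(unclass_config(out$config)),
            vapply(unclass_config(out$config),
                   function(v) paste(format(v), collapse = " "),
                   character(1))),
    ""
  )
  for (ut in c("new", "long_term")) {
    tr <- out$trend[[ut]]
    lines <- c(lines, sprintf("Trend, %s users (%% of yearly cohort):", ut))
    for (fy in unique(tr$fiscal_year)) {
      row <- tr[tr$fiscal_year == fy, ]
      lines <- c(lines, sprintf(
        "  FY%d (n=%d): %s", fy, row$denominator[1],
        paste(sprintf("%s %s", row$category,
                      ifelse(is.na(row$pct), "-", format_pct(row$pct))),
              collapse = "  ")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$cohort_result)
  cat(sprintf("  fiscal years: %s\n",
              paste(unique(x$trend$new$fiscal_year), collapse = ", ")))
  invisible(x)
}

# Run manifest: configuration snapshot, input/output digests, package
# version, per-file row counts. Exactly one manifest per output directory.
write_manifest <- function(out_dir, stage, config, files) {
  paths <- file.path(out_dir, files)
  info <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(paths)),
    rows = vapply(paths, function(p) {
      if (grepl("\\.csv$", p)) length(readr::read_lines(p,
                                                        progress = FALSE)) - 1L
      else NA_integer_
    }, integer(1))
  )
  manifest <- list(
    stage = stage,
    tool = "hypnorx",
    version = as.character(utils::packageVersion("hypnorx")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    files = purrr::pmap(info, function(file, md5, rows) {
      list(file = file, md5 = md5, rows = rows)
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
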