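MOA_CLASSES <- c("BZD", "Z_DRUG", "MRA", "ORA", "OTHER")
DURATION_TYPES <- c("long", "intermediate", "short", "ultrashort", "none")

#' The built-in hypnotic formulary
#'
#' The 23 oral hypnotics indicated for insomnia in Japan during the study
#' window, keyed by generic name and classified along two axes:
#'
#' * `moa_class` — the five-way mechanism-of-action taxonomy: `BZD`
#'   (benzodiazepine GABA-A receptor agonists, 12 drugs), `Z_DRUG`
#'   (non-benzodiazepine GABA-A receptor agonists, 3), `MRA` (melatonin
#'   receptor agonist: ramelteon), `ORA` (orexin receptor antagonist:
#'   suvorexant), and `OTHER` (barbiturates and older sedatives, 7).
#' * `duration_type` — action-duration subtype for GABA-A agonists only
#'   (`long`, `intermediate`, `short`, `ultrashort`); `none` for the other
#'   classes, which never enter duration-type tabulations.
#'
#' `max_days_per_rx` is the Japanese regulatory cap on days supplied per
#' prescription; `NA` means unrestricted. Phenobarbital's cap is a range
#' (30-90 days) in the regulations; the permissive bound 90 is stored so the
#' advisory QC flag never false-positives. Three older drugs (haloxazolam,
#' nimetazepam, rilmazafone) have no ATC code; matching is always by generic
#' name, never by ATC. Lemborexant is deliberately absent: it was not
#' marketed in Japan in the study window.
#'
#' The same table ships as a delimited resource at
#' `system.file("extdata", "hypnotic_formulary.tsv", package = "hypnorx")`;
#' user-supplied dictionaries in that format can extend or override the
#' built-in one via [read_formulary()].
#'
#' @return A tibble with columns `generic_name`, `moa_class`,
#'   `duration_type`, `atc_code`, `max_days_per_rx`.
#' @examples
#' dplyr::count(hypnotic_formulary(), moa_class)
#' @export
hypnotic_formulary <- function() {
  fm <- tibble::tribble(
    ~generic_name,              ~moa_class, ~duration_type,  ~atc_code, ~max_days_per_rx,
    "Flurazepam",                "BZD",     "long",          "N05CD01", 30L,
    "Quazepam",                  "BZD",     "long",          "N05CD10", 30L,
    "Haloxazolam",               "BZD",     "long",          NA,        30L,
    "Nitrazepam",                "BZD",     "intermediate",  "N05CD02", 90L,
    "Flunitrazepam",             "BZD",     "intermediate",  "N05CD03", 30L,
    "Estazolam",                 "BZD",     "intermediate",  "N05CD04", 30L,
    "Nimetazepam",               "BZD",     "intermediate",  NA,        30L,
    "Lormetazepam",              "BZD",     "short",         "N05CD06", 30L,
    "Brotizolam",                "BZD",     "short",         "N05CD09", 30L,
    "Etizolam",                  "BZD",     "short",         "N05BA19", 30L,
    "Rilmazafone hydrochloride", "BZD",     "short",         NA,        NA,
    "Triazolam",                 "BZD",     "ultrashort",    "N05CD05", 30L,
    "Zopiclone",                 "Z_DRUG",  "ultrashort",    "N05CF01", 30L,
    "Zolpidem tartrate",         "Z_DRUG",  "ultrashort",    "N05CF02", 30L,
    "Eszopiclone",               "Z_DRUG",  "ultrashort",    "N05CF04", NA,
    "Ramelteon",                 "MRA",     "none",          "N05CH02", NA,
    "Suvorexant",                "ORA",     "none",          "N05CM19", NA,
    "Phenobarbital",             "OTHER",   "none",          "N03AA02", 90L,
    "Pentobarbital calcium",     "OTHER",   "none",          "N05CA01", 14L,
    "Amobarbital",               "OTHER",   "none",          "N05CA02", 14L,
    "Barbital",                  "OTHER",   "none",          "N05CA04", 14L,
    "Chloral hydrate",           "OTHER",   "none",          "N05CC01", NA,
    "Bromovalerylurea",          "OTHER",   "none",          "N05CM03", NA,
    "Triclofos sodium",          "OTHER",   "none",          "N05CM07", NA
  )
  fm$max_days_per_rx <- as.integer(fm$max_days_per_rx)
  fm
}

#' Read a drug dictionary from a delimited file
#'
#' Reads a tab- or comma-separated file mirroring the built-in formulary's
#' columns. Entries with the same `generic_name` (case-insensitive) as a
#' built-in drug override it when `base` is supplied.
#'
#' @param path Path to the dictionary file.
#' @param base Optional base dictionary to extend/override (e.g.
#'   [hypnotic_formulary()]); `NULL` reads the file standalone.
#' @return A dictionary tibble.
#' @export
read_formulary <- function(path, base = NULL) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  fm <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    generic_name = readr::col_character(),
    moa_class = readr::col_character(),
    duration_type = readr::col_character(),
    atc_code = readr::col_character(),
    max_days_per_rx = readr::col_integer()
  ), progress = FALSE)
  if (!is.null(base)) {
    keep <- !tolower(base$generic_name) %in% tolower(fm$generic_name)
    fm <- dplyr::bind_rows(base[keep, ], fm)
  }
  validate_formulary(fm)
  fm
}

validate_formulary <- function(fm) {
  stopifnot(all(fm$moa_class %in% MOA_CLASSES),
            all(fm$duration_type %in% DURATION_TYPES),
            !any(duplicated(tolower(fm$generic_name))))
  # duration subtypes exist exactly for the GABA-A agonist classes
  gaba <- fm$moa_class %in% c("BZD", "Z_DRUG")
  if (any(fm$duration_type[gaba] == "none") ||
      any(fm$duration_type[!gaba] != "none")) {
    stop("duration_type must be set for BZD/Z_DRUG entries and 'none' otherwise",
         call. = FALSE)
  }
  invisible(fm)
}

#' Look up a drug in the dictionary
#'
#' Case-insensitive exact match on generic name. Unknown names are an error
#' (the pipeline default is to abort rather than silently drop a claim);
#' callers that prefer to drop can catch the condition, which carries the
#' offending name in its message.
#'
#' @param name Generic drug name.
#' @param dictionary A dictionary tibble; default the built-in formulary.
#' @return The matching one-row entry.
#' @examples
#' classify_drug("ramelteon")$moa_class
#' @export
classify_drug <- function(name, dictionary = hypnotic_formulary()) {
  stopifnot(length(name) == 1, nrow(dictionary) > 0)
  hit <- dictionary[tolower(dictionary$generic_name) == tolower(name), ]
  if (nrow(hit) != 1) {
    stop(sprintf("unknown drug name: '%s'", name), call. = FALSE)
  }
  hit
}

# vectorized classification used by the pipeline: left-join on lowercased
# name, abort listing every unknown name at once
classify_claims <- function(claims, dictionary = hypnotic_formulary()) {
  dict <- dictionary %>% dplyr::mutate(.key = tolower(.data$generic_name)) %>%
    dplyr::select(".key", "moa_class", "duration_type", "max_days_per_rx")
  out <- claims %>%
    dplyr::mutate(.key = tolower(.data$generic_name)) %>%
    dplyr::left_join(dict, by = ".key") %>%
    dplyr::select(-".key")
  if (anyNA(out$moa_class)) {
    bad <- unique(claims$generic_name[is.na(out$moa_class)])
    stop("unknown drug name: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Flag prescriptions exceeding the per-drug day cap
#'
#' Advisory quality-control check: `TRUE` when `days_supplied` exceeds the
#' drug's regulatory maximum days per prescription, never for unrestricted
#' drugs. Flagged claims are reported, not excluded.
#'
#' @param days_supplied Integer vector of days supplied.
#' @param entry A one-row dictionary entry ([classify_drug()] output), or a
#'   vector of caps (`NA` = unrestricted) recycled against `days_supplied`.
#' @return Logical vector.
#' @examples
#' check_rx_length(31, classify_drug("Triazolam"))
#' @export
check_rx_length <- function(days_supplied, entry) {
  cap <- if (is.data.frame(entry)) entry$max_days_per_rx else entry
  !is.na(cap) & days_supplied > cap
}
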