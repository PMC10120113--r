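ARCHETYPES <- c("incident_starter", "persistent_user", "switcher",
                "intermittent_user", "ineligible_decoy")
DECOY_KINDS <- c("no_insomnia_dx", "age_out_of_range",
                 "insufficient_enrollment", "narcolepsy",
                 "inpatient_at_index", "prn_only_at_index",
                 "multi_prescriber_overlap_at_index")
MOA_MIX_CATEGORIES <- c("BZD", "Z_DRUG", "MRA", "ORA", "OTHER", "multiple")
# two-class combinations drawn when a member's category is "multiple";
# weighted toward the BZD + z-drug pairing that dominates real combination
# prescribing
MULTI_COMBOS <- c("BZD+Z_DRUG" = 0.50, "BZD+MRA" = 0.10, "BZD+ORA" = 0.15,
                  "Z_DRUG+MRA" = 0.10, "Z_DRUG+ORA" = 0.15)

#' Scenario configuration for the synthetic claims generator
#'
#' Defaults emulate the study conditions of the source setting: the
#' age/sex margins of the pooled 2018-2019 new-user cohort, index MOA-mix
#' weights matching the observed 2018-2019 pattern distributions for new
#' (starter) and long-term (persister) users, baseline psychiatric
#' comorbidity prevalences per user type, and an archetype mix of 40%
#' incident starters, 25% persistent users, 15% switchers, 15% intermittent
#' users and 5% ineligible decoys.
#'
#' @param n_members Number of members to generate.
#' @param fiscal_years Fiscal years the scenario targets (each member is
#'   planted in one of them).
#' @param age_distribution Named weights over the four age groups
#'   `20-34`, `35-49`, `50-64`, `65-74`.
#' @param sex_split_male Proportion male.
#' @param archetype_mix Named weights over the five archetypes.
#' @param moa_mix_new,moa_mix_longterm Named weights over
#'   `BZD`, `Z_DRUG`, `MRA`, `ORA`, `OTHER`, `multiple` for starters and
#'   persisters respectively; switchers and intermittent users draw from
#'   the single-class part of `moa_mix_new`, renormalized.
#' @param comorbidity_prevalence A list with elements `new` and
#'   `long_term`, each a named probability per comorbidity category.
#' @param prn_rate,multi_prescriber_rate,narcolepsy_rate Contamination
#'   probabilities, all 0 by default (acceptance scenarios run clean;
#'   robustness scenarios switch them on).
#' @param chaining_slack_days Uncovered gap, in days, between consecutive
#'   refills in a persister's chain; recovery is exact whenever the
#'   analysis `grace_days` is at least this slack (and below the 76-day
#'   gaps that keep intermittent users fragmented).
#' @param seed Integer seed; generation is fully deterministic given the
#'   scenario.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(
    n_members = 1000L,
    fiscal_years = 2018:2019,
    age_distribution = c("20-34" = 0.264, "35-49" = 0.358,
                         "50-64" = 0.321, "65-74" = 0.057),
    sex_split_male = 0.541,
    archetype_mix = c(incident_starter = 0.40, persistent_user = 0.25,
                      switcher = 0.15, intermittent_user = 0.15,
                      ineligible_decoy = 0.05),
    moa_mix_new = c(BZD = 0.320, Z_DRUG = 0.402, MRA = 0.061,
                    ORA = 0.187, OTHER = 0.002, multiple = 0.028),
    moa_mix_longterm = c(BZD = 0.508, Z_DRUG = 0.256, MRA = 0.010,
                         ORA = 0.038, OTHER = 0.006, multiple = 0.182),
    comorbidity_prevalence = list(
      new = c(substance_use = 0.010, schizophrenia_spectrum = 0.036,
              bipolar = 0.024, depressive = 0.153, anxiety = 0.107,
              neurocognitive = 0.001, other_psychiatric = 0.153),
      long_term = c(substance_use = 0.029, schizophrenia_spectrum = 0.271,
                    bipolar = 0.177, depressive = 0.592, anxiety = 0.239,
                    neurocognitive = 0.003, other_psychiatric = 0.378)),
    prn_rate = 0, multi_prescriber_rate = 0, narcolepsy_rate = 0,
    chaining_slack_days = 0L,
    seed = 1L) {
  chk_weights <- function(w, nm) {
    if (abs(sum(w) - 1) > 1e-9) {
      stop(nm, " weights must sum to 1", call. = FALSE)
    }
  }
  stopifnot(n_members >= 1, length(fiscal_years) >= 1,
            identical(names(age_distribution), AGE_GROUPS),
            identical(names(archetype_mix), ARCHETYPES),
            identical(names(moa_mix_new), MOA_MIX_CATEGORIES),
            identical(names(moa_mix_longterm), MOA_MIX_CATEGORIES),
            sex_split_male >= 0, sex_split_male <= 1,
            prn_rate >= 0, prn_rate <= 1,
            multi_prescriber_rate >= 0, multi_prescriber_rate <= 1,
            narcolepsy_rate >= 0, narcolepsy_rate <= 1,
            chaining_slack_days >= 0, chaining_slack_days <= 45)
  chk_weights(age_distribution, "age_distribution")
  chk_weights(archetype_mix, "archetype_mix")
  chk_weights(moa_mix_new, "moa_mix_new")
  chk_weights(moa_mix_longterm, "moa_mix_longterm")
  structure(list(
    n_members = as.integer(n_members),
    fiscal_years = as.integer(sort(fiscal_years)),
    age_distribution = age_distribution,
    sex_split_male = sex_split_male,
    archetype_mix = archetype_mix,
    moa_mix_new = moa_mix_new,
    moa_mix_longterm = moa_mix_longterm,
    comorbidity_prevalence = comorbidity_prevalence,
    prn_rate = prn_rate,
    multi_prescriber_rate = multi_prescriber_rate,
    narcolepsy_rate = narcolepsy_rate,
    chaining_slack_days = as.integer(chaining_slack_days),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Analysis configuration matched to a scenario
#'
#' Convenience: an [analysis_config()] whose study window spans exactly the
#' scenario's fiscal years and whose grace period matches (or exceeds) the
#' scenario's chaining slack, the settings under which planted labels are
#' recovered exactly.
#'
#' @param scenario A [scenario_config()].
#' @param grace_days Episode grace; default `max(30, chaining slack)`.
#' @param ... Further arguments to [analysis_config()].
#' @return An `analysis_config`.
#' @export
matched_config <- function(scenario, grace_days = NULL, ...) {
  if (is.null(grace_days)) {
    grace_days <- max(30L, scenario$chaining_slack_days)
  }
  yrs <- range(scenario$fiscal_years)
  analysis_config(
    study_start = as.Date(sprintf("%d-04-01", yrs[1])),
    study_end = as.Date(sprintf("%d-03-31", yrs[2] + 1L)),
    grace_days = grace_days, seed = scenario$seed, ...)
}

# random generic name of a class, vectorized over class
pick_drugs <- function(classes, fm) {
  vapply(classes, function(cl) {
    pool <- fm$generic_name[fm$moa_class == cl]
    pool[sample.int(length(pool), 1)]
  }, character(1), USE.NAMES = FALSE)
}

drug_cap <- function(names, fm) {
  fm$max_days_per_rx[match(tolower(names), tolower(fm$generic_name))]
}

chain_supply <- function(names, fm) {
  cap <- drug_cap(names, fm)
  as.integer(pmin(30L, dplyr::coalesce(cap, 999L)))
}

#' Generate a synthetic claims dataset with ground-truth labels
#'
#' Archetype-first generation: each member's intended classification is
#' drawn first, then claims are synthesized to realize it.
#'
#' * *Incident starters* have an empty 12-month baseline and a single index
#'   prescription (two, for a multiple-MOA category) accompanied by an
#'   outpatient insomnia (G470) diagnosis.
#' * *Persistent users* carry a same-class refill chain starting at least
#'   200 days before an index date in the first weeks of their fiscal
#'   year, with inter-refill gaps equal to the scenario's chaining slack —
#'   a long-term user under any grace period at or above that slack.
#' * *Switchers* break the 180-day single-class rule by construction: one
#'   class for ~90 covered days, then a switch to the index class 60 days
#'   before index.
#' * *Intermittent users* have sporadic 14-day claims 90 days apart, so no
#'   chain survives any grace period below 76 days, and a non-empty
#'   baseline: neither new nor long-term.
#' * *Ineligible decoys* each violate exactly one eligibility or exclusion
#'   rule (missing insomnia diagnosis, age out of range, short enrollment,
#'   narcolepsy, hospitalization at index, as-needed-only at index, or
#'   overlapping prescriptions from two institutions at index).
#'
#' Because a persister's (or switcher's, or intermittent user's) pre-index
#' claims reach ~5-7 months back, the first of those claims is itself an
#' index with an empty baseline in the *preceding* fiscal year; when that
#' year is part of the scenario, the ground truth records the member as a
#' new user there — real claims data shows exactly this pattern, and the
#' generator accounts for it exactly.
#'
#' @param scenario A [scenario_config()].
#' @param dictionary Drug dictionary (drugs are drawn from it).
#' @return A list of class `synthetic_claims`: `dataset` (a validated
#'   [claims_dataset()]), `truth` (tibble: `member_id`, `fiscal_year`,
#'   `status`, `index_moa_category`, `archetype`), and `scenario`.
#' @export
simulate_claims <- function(scenario, dictionary = hypnotic_formulary()) {
  stopifnot(inherits(scenario, "scenario_config"))
  withr::with_seed(scenario$seed, simulate_claims_impl(scenario, dictionary))
}

simulate_claims_impl <- function(sc, fm) {
  n <- sc$n_members
  slack <- sc$chaining_slack_days

  mem <- tibble::tibble(
    member_id = sprintf("M%06d", seq_len(n)),
    archetype = sample(ARCHETYPES, n, replace = TRUE,
                       prob = sc$archetype_mix),
    fiscal_year = sample(rep(sc$fiscal_years, 2), n, replace = TRUE),
    sex = ifelse(stats::runif(n) < sc$sex_split_male, "male", "female"),
    age_group = sample(AGE_GROUPS, n, replace = TRUE,
                       prob = sc$age_distribution)
  )
  # completed age at the member's earliest claim; capped at 73 so ageing
  # over a pre-index chain never crosses the 75 exclusion bound
  age_lo <- c("20-34" = 20L, "35-49" = 35L, "50-64" = 50L, "65-74" = 65L)
  age_hi <- c("20-34" = 34L, "35-49" = 49L, "50-64" = 64L, "65-74" = 73L)
  mem$age <- age_lo[mem$age_group] +
    floor(stats::runif(n) * (age_hi[mem$age_group] -
                               age_lo[mem$age_group] + 1L))

  mem$decoy_kind <- NA_character_
  is_decoy <- mem$archetype == "ineligible_decoy"
  mem$decoy_kind[is_decoy] <- sample(DECOY_KINDS, sum(is_decoy),
                                     replace = TRUE)
  mem$age[is_decoy & mem$decoy_kind == "age_out_of_range"] <- 18L

  # --- index MOA category -------------------------------------------------
  single_mix <- sc$moa_mix_new[MOA_CLASSES] / sum(sc$moa_mix_new[MOA_CLASSES])
  draw_cat <- function(k, mix) sample(names(mix), k, replace = TRUE,
                                      prob = mix)
  mem$category <- NA_character_
  grp <- function(a) mem$archetype == a
  mem$category[grp("incident_starter")] <-
    draw_cat(sum(grp("incident_starter")), sc$moa_mix_new)
  mem$category[is_decoy] <- draw_cat(sum(is_decoy), sc$moa_mix_new)
  mem$category[grp("persistent_user")] <-
    draw_cat(sum(grp("persistent_user")), sc$moa_mix_longterm)
  sw_int <- grp("switcher") | grp("intermittent_user")
  mem$category[sw_int] <- draw_cat(sum(sw_int), single_mix)

  is_multi <- mem$category == "multiple"
  mem$combo <- NA_character_
  mem$combo[is_multi] <- sample(names(MULTI_COMBOS), sum(is_multi),
                                replace = TRUE, prob = MULTI_COMBOS)
  mem$class_a <- ifelse(is_multi,
                        vapply(strsplit(mem$combo, "+", fixed = TRUE),
                               `[`, character(1), 1),
                        mem$category)
  mem$class_b <- ifelse(is_multi,
                        vapply(strsplit(mem$combo, "+", fixed = TRUE),
                               function(x) x[2], character(1)),
                        NA_character_)
  # switchers additionally need a distinct pre-switch class
  sw <- grp("switcher")
  mem$class_pre <- NA_character_
  mem$class_pre[sw] <- vapply(mem$class_a[sw], function(cl) {
    sample(setdiff(MOA_CLASSES, cl), 1)
  }, character(1))

  mem$drug_a <- pick_drugs(mem$class_a, fm)
  mem$drug_b <- ifelse(is.na(mem$class_b), NA_character_,
                       pick_drugs(ifelse(is.na(mem$class_b), "BZD",
                                         mem$class_b), fm))
  mem$drug_pre <- ifelse(is.na(mem$class_pre), NA_character_,
                         pick_drugs(ifelse(is.na(mem$class_pre), "BZD",
                                           mem$class_pre), fm))

  # --- index dates --------------------------------------------------------
  b <- fiscal_year_bounds(mem$fiscal_year)
  mem$step_a <- chain_supply(mem$drug_a, fm) + slack
  offset_max <- dplyr::case_when(
    mem$archetype == "persistent_user" ~ pmin(mem$step_a, 30L) - 1L,
    mem$archetype == "switcher" ~ 29L,
    mem$archetype == "intermittent_user" ~ 89L,
    TRUE ~ 359L
  )
  mem$index_date <- b$fy_start +
    floor(stats::runif(n) * (offset_max + 1L))

  # --- institutions -------------------------------------------------------
  n_inst <- max(20L, n %/% 50L)
  institutions <- tibble::tibble(
    institution_id = sprintf("I%04d", seq_len(n_inst + 1L)),
    primary_department = c(
      ifelse(stats::runif(n_inst) < 0.35, "psychiatry", "other"), "other"),
    n_beds = c(ifelse(stats::runif(n_inst) < 0.75, 0L,
                      20L + floor(stats::runif(n_inst) * 280L)), 0L)
  )
  # the spare last institution is the decoys' second prescriber
  second_inst <- institutions$institution_id[n_inst + 1L]
  mem$institution_id <- sample(institutions$institution_id[seq_len(n_inst)],
                               n, replace = TRUE)

  # --- prescription claims ------------------------------------------------
  rx_parts <- list()
  supply_of <- function(drugs) {
    s <- sample(c(14L, 28L, 30L), length(drugs), replace = TRUE)
    cap <- drug_cap(drugs, fm)
    as.integer(pmin(s, dplyr::coalesce(cap, 999L)))
  }
  claim_row <- function(m, date, drug, supply, prn = FALSE,
                        inst = m$institution_id, setting = "outpatient") {
    tibble::tibble(member_id = m$member_id, dispense_date = date,
                   generic_name = drug, days_supplied = supply,
                   bedtime_flag = TRUE, prn_flag = prn,
                   institution_id = inst, setting = setting)
  }

  st <- mem[grp("incident_starter") | is_decoy, ]
  prn_decoy <- !is.na(st$decoy_kind) &
    st$decoy_kind == "prn_only_at_index"
  rx_parts$starter <- claim_row(st, st$index_date, st$drug_a,
                                supply_of(st$drug_a), prn = prn_decoy)
  st_b <- st[!is.na(st$drug_b), ]
  if (nrow(st_b) > 0) {
    prn_b <- !is.na(st_b$decoy_kind) &
      st_b$decoy_kind == "prn_only_at_index"
    rx_parts$starter_b <- claim_row(st_b, st_b$index_date, st_b$drug_b,
                                    supply_of(st_b$drug_b), prn = prn_b)
  }
  # second-prescriber decoys: an overlapping same-day claim from another
  # institution
  ov <- mem[is_decoy &
              mem$decoy_kind == "multi_prescriber_overlap_at_index", ]
  if (nrow(ov) > 0) {
    rx_parts$overlap <- claim_row(ov, ov$index_date, ov$drug_a,
                                  supply_of(ov$drug_a), inst = second_inst)
  }

  pe <- mem[grp("persistent_user"), ]
  if (nrow(pe) > 0) {
    n_claims <- ceiling(200L / pe$step_a) + 1L  # j = 0..J, J*step >= 200
    pe_long <- pe[rep(seq_len(nrow(pe)), n_claims), ]
    j <- unlist(lapply(n_claims, function(k) seq_len(k) - 1L))
    j_max <- rep(n_claims - 1L, n_claims)
    # neither the index claim (j = 0) nor the chain's first claim (j = J,
    # the prior-year echo index) may be PRN, or a planted label would flip
    rx_parts$persister <- claim_row(
      pe_long, pe_long$index_date - j * pe_long$step_a, pe_long$drug_a,
      chain_supply(pe_long$drug_a, fm),
      prn = j > 0 & j < j_max & stats::runif(length(j)) < sc$prn_rate)
    pe_b <- pe[!is.na(pe$drug_b), ]
    if (nrow(pe_b) > 0) {
      rx_parts$persister_b <- claim_row(pe_b, pe_b$index_date, pe_b$drug_b,
                                        supply_of(pe_b$drug_b))
    }
    extra <- pe[stats::runif(nrow(pe)) < sc$multi_prescriber_rate, ]
    if (nrow(extra) > 0) {
      # same class, second institution, covered span well before index:
      # never an index-day overlap, so the label is untouched
      rx_parts$persister_extra <- claim_row(
        extra, extra$index_date - 100L, extra$drug_a, 14L,
        inst = second_inst)
    }
  }

  sw_m <- mem[sw, ]
  if (nrow(sw_m) > 0) {
    pre_supply <- chain_supply(sw_m$drug_pre, fm)
    idx_supply <- chain_supply(sw_m$drug_a, fm)
    for (k in c(150L, 120L, 90L)) {
      # k = 150 is the prior-year echo index: keep it non-PRN
      rx_parts[[paste0("sw_pre_", k)]] <-
        claim_row(sw_m, sw_m$index_date - k, sw_m$drug_pre, pre_supply,
                  prn = k < 150L & stats::runif(nrow(sw_m)) < sc$prn_rate)
    }
    for (k in c(60L, 30L, 0L)) {
      rx_parts[[paste0("sw_idx_", k)]] <-
        claim_row(sw_m, sw_m$index_date - k, sw_m$drug_a, idx_supply,
                  prn = k > 0 & stats::runif(nrow(sw_m)) < sc$prn_rate)
    }
  }

  it <- mem[grp("intermittent_user"), ]
  if (nrow(it) > 0) {
    for (k in c(180L, 90L, 0L)) {
      # k = 180 is the prior-year echo index: keep it non-PRN
      rx_parts[[paste0("int_", k)]] <-
        claim_row(it, it$index_date - k, it$drug_a, 14L,
                  prn = k == 90L & stats::runif(nrow(it)) < sc$prn_rate)
    }
  }

  prescriptions <- dplyr::bind_rows(rx_parts) %>%
    dplyr::arrange(.data$member_id, .data$dispense_date,
                   .data$generic_name)

  # --- contamination: planted narcolepsy ---------------------------------
  narco_extra <- mem$member_id[!is_decoy &
                                 stats::runif(n) < sc$narcolepsy_rate]
  has_narco <- mem$member_id %in% narco_extra |
    (is_decoy & mem$decoy_kind == "narcolepsy")

  # --- diagnoses ----------------------------------------------------------
  no_dx <- is_decoy & mem$decoy_kind == "no_insomnia_dx"
  g470 <- prescriptions %>%
    dplyr::filter(!.data$member_id %in% mem$member_id[no_dx]) %>%
    dplyr::distinct(.data$member_id, .data$dispense_date) %>%
    dplyr::transmute(member_id = .data$member_id,
                     claim_date = .data$dispense_date,
                     icd10_code = "G470", setting = "outpatient")
  dx_parts <- list(g470 = g470)
  if (any(has_narco)) {
    nm <- mem[has_narco, ]
    dx_parts$narco <- tibble::tibble(
      member_id = nm$member_id, claim_date = nm$index_date,
      icd10_code = "G474", setting = "outpatient")
  }
  inpat <- mem[is_decoy & mem$decoy_kind == "inpatient_at_index", ]
  if (nrow(inpat) > 0) {
    dx_parts$inpatient <- tibble::tibble(
      member_id = inpat$member_id, claim_date = inpat$index_date,
      icd10_code = "J18", setting = "inpatient")
  }
  dx_parts$comorbid <- comorbidity_claims(mem, sc)
  diagnoses <- dplyr::bind_rows(dx_parts) %>%
    dplyr::arrange(.data$member_id, .data$claim_date, .data$icd10_code)

  # --- enrollment and demographics ---------------------------------------
  earliest <- prescriptions %>%
    dplyr::group_by(.data$member_id) %>%
    dplyr::summarise(first_claim = min(.data$dispense_date),
                     .groups = "drop")
  mem <- mem %>% dplyr::left_join(earliest, by = "member_id")
  global_end <- max(fiscal_year_bounds(max(sc$fiscal_years))$fy_end) + 30L
  short_enrol <- is_decoy & mem$decoy_kind == "insufficient_enrollment"
  enrollment <- tibble::tibble(
    member_id = mem$member_id,
    start_date = dplyr::if_else(short_enrol,
                                mem$index_date - 150L,
                                mem$first_claim - 400L),
    end_date = global_end
  )
  first_ym <- as.integer(format(mem$first_claim, "%Y")) * 12L +
    as.integer(format(mem$first_claim, "%m")) - 1L
  birth_ym <- first_ym - (mem$age * 12L +
                            floor(stats::runif(n) * 12L))
  members <- tibble::tibble(
    member_id = mem$member_id,
    birth_year_month = sprintf("%04d-%02d", birth_ym %/% 12L,
                               birth_ym %% 12L + 1L),
    sex = mem$sex
  )

  ds <- claims_dataset(members, enrollment, diagnoses, prescriptions,
                       institutions)
  truth <- ground_truth(mem, has_narco, sc)
  structure(list(dataset = ds, truth = truth, scenario = sc),
            class = "synthetic_claims")
}

# comorbidity diagnosis claims drawn per prevalence into the 12-month
# baseline window before each member's planted index
comorbidity_claims <- function(mem, sc) {
  code_pool <- list(
    substance_use = c("F10", "F12", "F17"),
    schizophrenia_spectrum = c("F20", "F25", "F29"),
    bipolar = c("F30", "F31"),
    depressive = c("F32", "F33"),
    anxiety = c("F40", "F41", "F42"),
    neurocognitive = c("F00", "G30"),
    other_psychiatric = c("F43", "F45", "F84", "F03")
  )
  prev_type <- ifelse(mem$archetype == "persistent_user", "long_term",
                      "new")
  out <- list()
  for (cat in COMORBIDITIES) {
    p <- vapply(prev_type,
                function(t) sc$comorbidity_prevalence[[t]][[cat]],
                numeric(1), USE.NAMES = FALSE)
    hit <- stats::runif(nrow(mem)) < p
    if (!any(hit)) next
    m <- mem[hit, ]
    pool <- code_pool[[cat]]
    out[[cat]] <- tibble::tibble(
      member_id = m$member_id,
      claim_date = m$index_date -
        (1L + floor(stats::runif(nrow(m)) * 360L)),
      icd10_code = pool[1L + floor(stats::runif(nrow(m)) * length(pool))],
      setting = "outpatient")
  }
  dplyr::bind_rows(out)
}

# planted labels per member-year, including the chain-induced new-user
# appearance in the preceding fiscal year
ground_truth <- function(mem, has_narco, sc) {
  combo_of <- function(class_a, class_b) {
    ifelse(is.na(class_b), class_a,
           mapply(function(a, b) moa_combo_label(c(a, b)), class_a,
                  class_b, USE.NAMES = FALSE))
  }
  status <- dplyr::case_when(
    has_narco ~ "excluded:narcolepsy",
    mem$archetype == "incident_starter" ~ "new",
    mem$archetype == "persistent_user" ~ "long_term",
    mem$archetype %in% c("switcher", "intermittent_user") ~ "neither",
    TRUE ~ paste0("excluded:", mem$decoy_kind)
  )
  main <- tibble::tibble(
    member_id = mem$member_id,
    fiscal_year = mem$fiscal_year,
    status = status,
    index_moa_category = combo_of(mem$class_a, mem$class_b),
    archetype = mem$archetype
  )
  # earlier-year echo: the first pre-index claim opens an index with an
  # empty baseline in fiscal_year - 1
  echo_src <- mem[mem$archetype %in%
                    c("persistent_user", "switcher", "intermittent_user") &
                    (mem$fiscal_year - 1L) %in% sc$fiscal_years, ]
  echo <- if (nrow(echo_src) == 0) main[0, ] else tibble::tibble(
    member_id = echo_src$member_id,
    fiscal_year = echo_src$fiscal_year - 1L,
    status = ifelse(echo_src$member_id %in% mem$member_id[has_narco],
                    "excluded:narcolepsy", "new"),
    index_moa_category = ifelse(echo_src$archetype == "switcher",
                                echo_src$class_pre, echo_src$class_a),
    archetype = echo_src$archetype
  )
  dplyr::bind_rows(main, echo) %>%
    dplyr::arrange(.data$member_id, .data$fiscal_year)
}

#' @export
print.synthetic_claims <- function(x, ...) {
  cat("<synthetic_claims>\n")
  cat(sprintf("  %d members, fiscal years %s, seed %d\n",
              x$scenario$n_members,
              paste(x$scenario$fiscal_years, collapse = ", "),
              x$scenario$seed))
  print(x$dataset)
  cat(sprintf("  ground truth: %d member-years\n", nrow(x$truth)))
  invisible(x)
}

#' Cross-tabulate planted labels against pipeline assignments
#'
#' Joins the generator's ground truth with a [build_cohort()] result and
#' tabulates intended versus assigned status, and intended versus assigned
#' index MOA category for the member-years included in a cohort. With
#' matched settings (analysis grace at or above the scenario's chaining
#' slack, study window equal to the scenario years) the tables are
#' diagonal.
#'
#' @param truth Ground-truth tibble from [simulate_claims()].
#' @param result A `cohort_result` from [build_cohort()].
#' @return A list: `status` (tibble `intended` x `assigned` x `n`), `moa`
#'   (likewise, included member-years only), `n_mismatch` (status
#'   disagreements), `n_member_years`.
#' @export
recovery_report <- function(truth, result) {
  audit <- result$audit %>%
    dplyr::mutate(assigned = dplyr::case_when(
      .data$status == "included_new" ~ "new",
      .data$status == "included_long_term" ~ "long_term",
      .data$reason_codes == "neither_user_type" ~ "neither",
      TRUE ~ paste0("excluded:", .data$reason_codes)))
  joined <- truth %>%
    dplyr::full_join(audit[c("member_id", "fiscal_year", "assigned")],
                     by = c("member_id", "fiscal_year")) %>%
    dplyr::mutate(
      intended = dplyr::coalesce(.data$status, "<absent>"),
      assigned = dplyr::coalesce(.data$assigned, "<absent>"))
  status_tab <- joined %>%
    dplyr::count(.data$intended, .data$assigned, name = "n")
  moa_tab <- truth %>%
    dplyr::inner_join(
      result$cohort[c("member_id", "fiscal_year", "index_moa_category")],
      by = c("member_id", "fiscal_year"),
      suffix = c("_intended", "_assigned")) %>%
    dplyr::count(intended = .data$index_moa_category_intended,
                 assigned = .data$index_moa_category_assigned, name = "n")
  list(status = status_tab, moa = moa_tab,
       n_mismatch = sum(status_tab$n[status_tab$intended !=
                                       status_tab$assigned]),
       n_member_years = nrow(joined))
}
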