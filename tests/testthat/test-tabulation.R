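test_that("index MOA categories pool classes and order combination labels", {
  single <- moa_category_at_index(
    tibble::tibble(generic_name = "Brotizolam"))
  expect_equal(single$kind, "single")
  expect_equal(single$combo_label, "BZD")

  combo <- moa_category_at_index(
    tibble::tibble(generic_name = c("Zolpidem tartrate", "Brotizolam")))
  expect_equal(combo$kind, "multiple")
  # label order is the fixed taxonomy order, not input order
  expect_equal(combo$combo_label, "BZD+Z_DRUG")

  # two benzodiazepines are a single MOA
  two_bzd <- moa_category_at_index(
    tibble::tibble(generic_name = c("Brotizolam", "Triazolam")))
  expect_equal(two_bzd$kind, "single")
  expect_equal(two_bzd$combo_label, "BZD")
})

test_that("hypnotic counts are distinct generic names with a 4+ bucket", {
  one <- n_hypnotics_at_index(tibble::tibble(generic_name = "Etizolam"))
  expect_equal(one$n, 1L)
  # same generic dispensed by two institutions still counts once
  dup <- n_hypnotics_at_index(
    tibble::tibble(generic_name = c("Etizolam", "etizolam")))
  expect_equal(dup$n, 1L)
  four <- n_hypnotics_at_index(tibble::tibble(
    generic_name = c("Etizolam", "Zopiclone", "Ramelteon", "Suvorexant")))
  expect_equal(four$bucket, "4+")
})

test_that("BZD duration categories collapse to the shared type or 2+", {
  expect_equal(bzd_duration_category(
    tibble::tibble(generic_name = "Triazolam")), "ultrashort")
  expect_equal(bzd_duration_category(
    tibble::tibble(generic_name = c("Brotizolam", "Estazolam"))),
    "two_or_more_types")
  # two drugs of the same type stay that type
  expect_equal(bzd_duration_category(
    tibble::tibble(generic_name = c("Brotizolam", "Etizolam"))), "short")
  # non-BZD claims alongside do not disturb the BZD typing
  expect_equal(bzd_duration_category(
    tibble::tibble(generic_name = c("Triazolam", "Suvorexant"))),
    "ultrashort")
  expect_error(bzd_duration_category(
    tibble::tibble(generic_name = "Suvorexant")), "no BZD")
})

test_that("comorbidity ranges follow the ICD-10 category boundaries", {
  win <- tibble::tibble(member_id = "m1",
                        baseline_start = as.Date("2018-01-01"),
                        baseline_end = as.Date("2018-12-31"))
  flag <- function(code, date = "2018-06-01") {
    comorbidity_flags(dx_claim("m1", date, code), win)
  }
  expect_true(flag("F32")$cm_depressive)
  expect_true(flag("F41")$cm_anxiety)
  # F43 is outside the F40-F42 anxiety range -> residual
  f43 <- flag("F43")
  expect_false(f43$cm_anxiety)
  expect_true(f43$cm_other_psychiatric)
  # unspecified dementia is NOT neurocognitive (Alzheimer's only)
  f03 <- flag("F03")
  expect_false(f03$cm_neurocognitive)
  expect_true(f03$cm_other_psychiatric)
  g30 <- flag("G30")
  expect_true(g30$cm_neurocognitive)
  expect_false(g30$cm_other_psychiatric)
  # subcodes inherit their category: F321 is depressive
  expect_true(flag("F321")$cm_depressive)
  # claims outside the window never flag
  outside <- flag("F32", "2019-02-01")
  expect_false(any(unlist(outside[-1])))
  # a member with no claims is present, all-FALSE
  none <- comorbidity_flags(dx_claim("m2", "2018-06-01", "F32"), win)
  expect_equal(nrow(none), 1)
  expect_false(any(unlist(none[-1])))
})

test_that("Wald intervals match the closed form and clip at the scale ends", {
  est <- proportion_ci(29892, 55263)
  p <- 29892 / 55263
  half <- qnorm(0.975) * sqrt(p * (1 - p) / 55263)
  expect_equal(est$ci_low, 100 * (p - half), tolerance = 1e-9)
  expect_equal(est$ci_high, 100 * (p + half), tolerance = 1e-9)

  zero <- proportion_ci(0, 10)
  expect_equal(zero$pct, 0)
  expect_equal(zero$ci_low, 0)

  sym <- proportion_ci(500, 1000)
  expect_equal(sym$pct, 50)
  expect_equal(sym$pct - sym$ci_low, sym$ci_high - sym$pct)
})

test_that("Wilson intervals match the score interval of prop.test", {
  for (case in list(c(5, 10), c(0, 10), c(29892, 55263), c(1, 1000))) {
    got <- proportion_ci(case[1], case[2], method = "wilson")
    ref <- prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(got$ci_low, 100 * ref[1], tolerance = 1e-9)
    expect_equal(got$ci_high, 100 * ref[2], tolerance = 1e-9)
  }
  # wilson lower bound exceeds wald's at count 0
  expect_gt(proportion_ci(0, 50, method = "wilson")$ci_low,
            proportion_ci(0, 50, method = "wald")$ci_low - 1e-12)
})

test_that("display rounding is half away from zero at one decimal", {
  expect_equal(round_half_away(0.05, 1), 0.1)
  expect_equal(round_half_away(2.25, 1), 2.3)
  expect_equal(round_half_away(-0.05, 1), -0.1)
  expect_equal(format_pct(54.0904), "54.1")
})

test_that("trend tables recover a planted single-class mix exactly", {
  # archetype-first generation: starters only, so every cohort member's
  # category is the drawn one
  sc <- scenario_config(
    n_members = 400, fiscal_years = 2019,
    archetype_mix = c(incident_starter = 1, persistent_user = 0,
                      switcher = 0, intermittent_user = 0,
                      ineligible_decoy = 0),
    moa_mix_new = c(BZD = 0.5, Z_DRUG = 0.3, MRA = 0.1, ORA = 0.1,
                    OTHER = 0, multiple = 0),
    seed = 5)
  sim <- simulate_claims(sc)
  res <- build_cohort(sim$dataset, matched_config(sc))
  tr <- trend_by_year(res, "new")
  expect_equal(sum(tr$count), 400)
  truth_counts <- table(factor(sim$truth$index_moa_category,
                               levels = c("BZD", "Z_DRUG", "MRA", "ORA",
                                          "OTHER")))
  got <- tr$count[match(names(truth_counts), as.character(tr$category))]
  expect_equal(got, as.integer(truth_counts), ignore_attr = TRUE)
  expect_equal(tr$count[tr$category == "multiple"], 0L)
  # percentages of one denominator group sum to 100
  expect_equal(sum(tr$pct), 100, tolerance = 1e-9)
})

test_that("an all-BZD cohort shows 100% BZD and zeros elsewhere", {
  ds <- ds_fixture(dplyr::bind_rows(
    rx_claim("m1", "2018-05-10"),
    rx_claim("m2", "2018-06-10", generic_name = "Triazolam")))
  tr <- trend_by_year(build_cohort(ds, test_config()), "new")
  tr18 <- tr[tr$fiscal_year == 2018, ]
  expect_equal(tr18$pct[tr18$category == "BZD"], 100)
  expect_equal(sum(tr18$count[tr18$category != "BZD"]), 0L)
})

test_that("empty forced years appear with zero denominators", {
  ds <- ds_fixture(rx_claim("m1", "2018-05-10"))
  tr <- trend_by_year(build_cohort(ds, test_config()), "new",
                      fiscal_years = 2017:2019)
  expect_setequal(unique(tr$fiscal_year), 2017:2019)
  empty <- tr[tr$fiscal_year == 2019, ]
  expect_true(all(empty$denominator == 0))
  expect_true(all(is.na(empty$pct)))
})

test_that("pattern tables nest denominators and conserve partitions", {
  sc <- scenario_config(n_members = 1500, seed = 23)
  sim <- simulate_claims(sc)
  res <- build_cohort(sim$dataset, matched_config(sc))
  for (ut in c("new", "long_term")) {
    pat <- pattern_distribution(res, ut, fiscal_years = 2018:2019)
    n_ut <- sum(res$cohort$user_type == ut)
    expect_equal(sum(pat$moa$count), n_ut)
    expect_equal(unique(pat$moa$denominator), n_ut)
    # within-BZD denominators count everyone prescribed a BZD at index
    n_bzd <- sum(grepl("BZD", res$cohort$index_moa_category) &
                   res$cohort$user_type == ut)
    expect_equal(unique(pat$bzd_duration$denominator), n_bzd)
    expect_equal(sum(pat$bzd_duration$count), n_bzd)
    expect_equal(sum(pat$bzd_duration$pct), 100, tolerance = 1e-9)
    # within-multiple denominators
    n_multi <- sum(res$cohort$index_moa_kind == "multiple" &
                     res$cohort$user_type == ut)
    expect_equal(sum(pat$multi_combo$count), n_multi)
  }
})

test_that("stratification never changes totals", {
  sc <- scenario_config(n_members = 800, seed = 31)
  sim <- simulate_claims(sc)
  res <- build_cohort(sim$dataset, matched_config(sc))
  plain <- trend_by_year(res, "new")
  for (strat in list("sex", "age_group", c("cm_depressive", "sex"))) {
    strat_tab <- trend_by_year(res, "new", by = strat)
    rolled <- stats::aggregate(count ~ fiscal_year + category, strat_tab,
                               sum)
    m <- merge(plain, rolled, by = c("fiscal_year", "category"),
               suffixes = c("_plain", "_strat"))
    expect_equal(m$count_strat, m$count_plain)
  }
  # patient-year pooling: a member indexed in both pooled years counts
  # twice
  dates <- seq(as.Date("2018-06-01"), as.Date("2019-08-01"), by = 30)
  ds <- ds_fixture(dplyr::bind_rows(lapply(dates, function(d) {
    rx_claim("mY", d, days_supplied = 30L)
  })))
  res2 <- build_cohort(ds, test_config())
  pat_new <- pattern_distribution(res2, "new", fiscal_years = 2018:2019)
  pat_lt <- pattern_distribution(res2, "long_term",
                                 fiscal_years = 2018:2019)
  expect_equal(sum(pat_new$moa$count) + sum(pat_lt$moa$count), 2)
})
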