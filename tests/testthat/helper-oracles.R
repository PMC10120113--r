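# Brute-force day-set oracles, independent of the interval-chaining
# implementations they check.

# union of covered days of closed intervals, as sorted integers
covered_days <- function(start, end) {
  sort(unique(unlist(mapply(seq, as.integer(start), as.integer(end),
                            SIMPLIFY = FALSE))))
}

# maximal runs over a day set, bridging uncovered gaps of at most
# `gap_days`; returns start/end pairs
day_runs <- function(days, gap_days = 0) {
  if (length(days) == 0) return(NULL)
  brk <- c(TRUE, diff(days) > gap_days + 1)
  run <- cumsum(brk)
  data.frame(start = tapply(days, run, min), end = tapply(days, run, max))
}

# per-member brute-force interval merging
oracle_merge <- function(intervals, max_gap_days = 0) {
  out <- lapply(split(intervals, intervals$member_id), function(g) {
    runs <- day_runs(covered_days(g$start_date, g$end_date), max_gap_days)
    tibble::tibble(member_id = g$member_id[1],
                   start_date = as.Date(runs$start, origin = "1970-01-01"),
                   end_date = as.Date(runs$end, origin = "1970-01-01"))
  })
  dplyr::arrange(dplyr::bind_rows(out), member_id, start_date)
}

# brute-force episode construction: per member x MOA class, runs over the
# per-day coverage bitmap; each claim is attributed to the run holding its
# dispense day
oracle_episodes <- function(claims, dictionary = hypnotic_formulary(),
                            grace_days = 0) {
  moa <- dictionary$moa_class[match(tolower(claims$generic_name),
                                    tolower(dictionary$generic_name))]
  stopifnot(!anyNA(moa))
  claims$moa_class <- moa
  groups <- split(claims, list(claims$member_id, claims$moa_class),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    runs <- day_runs(
      covered_days(g$dispense_date, g$dispense_date + g$days_supplied - 1),
      grace_days)
    n_claims <- vapply(seq_len(nrow(runs)), function(i) {
      sum(as.integer(g$dispense_date) >= runs$start[i] &
            as.integer(g$dispense_date) <= runs$end[i])
    }, integer(1))
    tibble::tibble(member_id = g$member_id[1], moa_class = g$moa_class[1],
                   start_date = as.Date(runs$start, origin = "1970-01-01"),
                   end_date = as.Date(runs$end, origin = "1970-01-01"),
                   n_claims = n_claims)
  })
  dplyr::arrange(dplyr::bind_rows(out), member_id, moa_class, start_date)
}

# random claim set over a ~400-day span for property tests
random_claims <- function(n_claims, member_id = "m1",
                          drugs = c("Brotizolam", "Zolpidem tartrate",
                                    "Ramelteon", "Suvorexant",
                                    "Chloral hydrate")) {
  tibble::tibble(
    member_id = member_id,
    dispense_date = as.Date("2018-01-01") + sample(0:400, n_claims,
                                                   replace = TRUE),
    generic_name = sample(drugs, n_claims, replace = TRUE),
    days_supplied = sample(c(1L, 7L, 14L, 28L, 30L), n_claims,
                           replace = TRUE)
  )
}
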