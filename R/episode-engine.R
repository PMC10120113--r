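#' Chain prescriptions into continuous-coverage episodes per MOA class
#'
#' The machinery behind the long-term-use rule ("continuous prescription of
#' the same mechanism of action"). Each claim covers the closed interval
#' `[dispense_date, dispense_date + days_supplied - 1]`. Within one member
#' and one MOA class — all generics of a class pool into a single stream, so
#' switching between two benzodiazepines never breaks a BZD episode — claims
#' are chained into one episode whenever the next claim starts no later than
#' the previous covered end + `grace_days` + 1. Overlapping claims (early
#' refills) extend coverage by interval union; unused supply is never
#' shifted forward ("stockpiled"). PRN-flagged claims contribute to coverage
#' like any other claim: the as-needed exclusion applies to patients at the
#' index date, not to claims during continuity (drop them beforehand for a
#' sensitivity run).
#'
#' @param claims Prescription claims (already restricted by the caller to
#'   the relevant stream, typically bedtime-flagged outpatient claims with a
#'   parseable date).
#' @param dictionary Drug dictionary; every `generic_name` must resolve,
#'   otherwise an error carrying the unknown names is raised.
#' @param grace_days Largest uncovered gap, in days, bridged within an
#'   episode. Default 30 (one typical refill under the prevailing 30-day
#'   caps); 0 and 7 are common sensitivity presets.
#' @return A tibble of episodes: `member_id`, `moa_class`, `start_date`,
#'   `end_date`, `n_claims`, sorted by member, class, start. Episodes of the
#'   same member and class are disjoint and separated by gaps >
#'   `grace_days`.
#' @examples
#' claims <- tibble::tibble(
#'   member_id = "m1",
#'   dispense_date = as.Date(c("2019-01-01", "2019-01-31")),
#'   generic_name = c("Brotizolam", "Triazolam"),
#'   days_supplied = 30L
#' )
#' build_episodes(claims, grace_days = 0)  # one pooled BZD episode
#' @export
build_episodes <- function(claims, dictionary = hypnotic_formulary(),
                           grace_days = 30L) {
  stopifnot(grace_days >= 0)
  empty <- tibble::tibble(member_id = character(), moa_class = character(),
                          start_date = as.Date(character()),
                          end_date = as.Date(character()),
                          n_claims = integer())
  if (nrow(claims) == 0) return(empty)
  stopifnot(!anyNA(claims$dispense_date), all(claims$days_supplied >= 1L))
  classified <- classify_claims(claims, dictionary)
  classified %>%
    dplyr::mutate(cov_start = .data$dispense_date,
                  cov_end = .data$dispense_date + .data$days_supplied - 1L) %>%
    dplyr::arrange(.data$member_id, .data$moa_class, .data$cov_start,
                   .data$cov_end) %>%
    dplyr::group_by(.data$member_id, .data$moa_class) %>%
    dplyr::mutate(
      prev_end = dplyr::lag(cummax(as.integer(.data$cov_end))),
      episode = cumsum(is.na(.data$prev_end) |
                         as.integer(.data$cov_start) >
                           .data$prev_end + grace_days + 1L)
    ) %>%
    dplyr::group_by(.data$member_id, .data$moa_class, .data$episode) %>%
    dplyr::summarise(start_date = min(.data$cov_start),
                     end_date = max(.data$cov_end),
                     n_claims = dplyr::n(), .groups = "drop") %>%
    dplyr::select("member_id", "moa_class", "start_date", "end_date",
                  "n_claims")
}

#' Find the episode covering a date
#'
#' Returns the unique episode of the given MOA class whose closed
#' `[start_date, end_date]` span contains `date`, or `NULL` when no episode
#' covers it. Disjointness of same-member, same-class episodes guarantees at
#' most one hit.
#'
#' @param episodes Episodes from [build_episodes()] (one member's, or pass
#'   `member_id` to restrict).
#' @param date A calendar date.
#' @param moa_class One of `BZD`, `Z_DRUG`, `MRA`, `ORA`, `OTHER`.
#' @param member_id Optional member filter when `episodes` spans members.
#' @return A one-row tibble, or `NULL`.
#' @export
episode_covering <- function(episodes, date, moa_class, member_id = NULL) {
  hit <- episodes[episodes$moa_class == moa_class &
                    episodes$start_date <= date &
                    episodes$end_date >= date, ]
  if (!is.null(member_id)) hit <- hit[hit$member_id == member_id, ]
  if (nrow(hit) == 0) return(NULL)
  if (nrow(hit) > 1) {
    stop("episodes are not disjoint: multiple episodes cover ", date,
         call. = FALSE)
  }
  hit
}

#' Days of continuous coverage from episode start through a date
#'
#' Inclusive day count `date - start_date + 1` for a date inside the
#' episode; the quantity compared against the 180-day long-term threshold.
#'
#' @param episode A one-row episode.
#' @param date A date within `[start_date, end_date]`.
#' @return Integer number of days.
#' @examples
#' ep <- tibble::tibble(start_date = as.Date("2019-01-01"),
#'                      end_date = as.Date("2019-12-31"))
#' continuous_days_before(ep, as.Date("2019-06-29"))  # 180
#' @export
continuous_days_before <- function(episode, date) {
  stopifnot(nrow(episode) == 1)
  if (date < episode$start_date || date > episode$end_date) {
    stop("date ", date, " is outside the episode", call. = FALSE)
  }
  as.integer(date - episode$start_date) + 1L
}
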