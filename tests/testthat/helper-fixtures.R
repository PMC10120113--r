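# Compact builders for hand-constructed claims datasets.

rx_claim <- function(member_id, dispense_date, generic_name = "Brotizolam",
                     days_supplied = 30L, bedtime_flag = TRUE,
                     prn_flag = FALSE, institution_id = "I1",
                     setting = "outpatient") {
  tibble::tibble(member_id = member_id,
                 dispense_date = as.Date(dispense_date),
                 generic_name = generic_name,
                 days_supplied = as.integer(days_supplied),
                 bedtime_flag = bedtime_flag, prn_flag = prn_flag,
                 institution_id = institution_id, setting = setting)
}

dx_claim <- function(member_id, claim_date, icd10_code = "G470",
                     setting = "outpatient") {
  tibble::tibble(member_id = member_id, claim_date = as.Date(claim_date),
                 icd10_code = icd10_code, setting = setting)
}

# fills in defaults: every referenced member born 1980-01, male, enrolled
# 2008-2021; every hypnotic claim accompanied by a same-day outpatient
# insomnia diagnosis unless `auto_dx = FALSE`; institutions default to
# non-psychiatric clinics
ds_fixture <- function(prescriptions = rx_claim("m1", "2018-05-10"),
                       diagnoses = NULL, members = NULL,
                       enrollment = NULL, institutions = NULL,
                       auto_dx = TRUE) {
  ids <- unique(c(prescriptions$member_id, diagnoses$member_id,
                  members$member_id))
  if (is.null(members)) {
    members <- tibble::tibble(member_id = ids,
                              birth_year_month = "1980-01", sex = "male")
  }
  if (is.null(enrollment)) {
    enrollment <- tibble::tibble(member_id = ids,
                                 start_date = as.Date("2008-01-01"),
                                 end_date = as.Date("2021-12-31"))
  }
  if (auto_dx) {
    auto <- prescriptions |>
      dplyr::filter(!is.na(dispense_date)) |>
      dplyr::distinct(member_id, dispense_date) |>
      dplyr::transmute(member_id, claim_date = dispense_date,
                       icd10_code = "G470", setting = "outpatient")
    diagnoses <- dplyr::bind_rows(diagnoses, auto)
  }
  if (is.null(diagnoses)) diagnoses <- dx_claim(character(0), character(0))
  if (is.null(institutions)) {
    institutions <- tibble::tibble(
      institution_id = unique(prescriptions$institution_id),
      primary_department = "other", n_beds = 0L)
  }
  claims_dataset(members, enrollment, diagnoses, prescriptions,
                 institutions)
}

test_config <- function(...) {
  analysis_config(study_start = as.Date("2017-04-01"),
                  study_end = as.Date("2020-03-31"), ...)
}
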