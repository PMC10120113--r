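# Claims exchange format

Five delimited text tables (UTF-8, header row; `.csv` comma-separated or
`.tsv` tab-separated). Dates are ISO 8601 (`YYYY-MM-DD`); all intervals are
closed and day-granular. Logical columns are `TRUE`/`FALSE`.

## members.csv
| column           | type      | notes                                   |
|------------------|-----------|-----------------------------------------|
| member_id        | text      | opaque, unique within a dataset         |
| birth_year_month | text      | `YYYY-MM`; claims carry month precision |
| sex              | text      | `male` or `female`                      |

## enrollment.csv
| column     | type | notes                                  |
|------------|------|----------------------------------------|
| member_id  | text | must exist in members                  |
| start_date | date | closed interval `[start_date, end_date]` |
| end_date   | date | `start_date <= end_date`               |

## diagnoses.csv
| column     | type | notes                                        |
|------------|------|----------------------------------------------|
| member_id  | text | must exist in members                        |
| claim_date | date |                                              |
| icd10_code | text | letter + 2-3 digits, e.g. `G470`, `F32`      |
| setting    | text | `outpatient` or `inpatient`                  |

## prescriptions.csv
| column         | type    | notes                                                 |
|----------------|---------|-------------------------------------------------------|
| member_id      | text    | must exist in members                                 |
| dispense_date  | date    | may be empty (missing prescription date)              |
| generic_name   | text    | formulary key; see hypnotic_formulary.tsv             |
| days_supplied  | integer | >= 1; coverage is `[dispense_date, dispense_date + days_supplied - 1]` |
| bedtime_flag   | logical | instruction is bedtime administration                 |
| prn_flag       | logical | *pro re nata* (as-needed) instruction                 |
| institution_id | text    | must exist in institutions                            |
| setting        | text    | `outpatient` or `inpatient`                           |

## institutions.csv
| column             | type    | notes                          |
|--------------------|---------|--------------------------------|
| institution_id     | text    | opaque, unique                 |
| primary_department | text    | `psychiatry` or `other`        |
| n_beds             | integer | >= 0; clinic 0-19, hospital 20+ |

## hypnotic_formulary.tsv
Drug dictionary: `generic_name`, `moa_class` (`BZD`, `Z_DRUG`, `MRA`, `ORA`,
`OTHER`), `duration_type` (`long`, `intermediate`, `short`, `ultrashort`;
`none` outside BZD/Z_DRUG), `atc_code` (`NA` where the drug has no ATC code),
`max_days_per_rx` (`NA` = unrestricted).
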