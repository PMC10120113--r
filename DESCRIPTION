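Package: hypnorx
Title: Hypnotic Prescribing Cohorts, Episodes and Trends from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for drug-utilization analysis of hypnotic
    prescribing in longitudinal health-insurance claims. Classifies oral
    hypnotics into five mechanism-of-action classes (benzodiazepines, z-drugs,
    melatonin receptor agonist, orexin receptor antagonist, others), chains
    dated prescriptions into continuous-coverage episodes with a configurable
    grace period, identifies new and long-term users per Japanese fiscal year
    under explicit eligibility and exclusion rules, and tabulates prescribing
    trends and patterns as proportions with two-sided 95% confidence
    intervals. Ships an archetype-first synthetic claims generator with
    ground-truth labels so every stage is testable without access to a
    proprietary claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
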