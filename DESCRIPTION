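Package: rxpersist
Title: Medication Persistence Analysis from Pharmacy Dispensing Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying persistence to drug classes from pharmacy
    claims: parsing free-text dosage instructions into daily tablet rates,
    building per-patient supply schedules with tablet carry-over, applying a
    refill-gap (grace period) rule to classify discontinuation and switching,
    censoring at death, long hospitalization, multi-dose (unit-bag)
    dispensing or end of follow-up, and estimating persistence with
    Kaplan-Meier curves and crude/adjusted Cox proportional-hazards ratios.
    Includes a synthetic-cohort generator that emulates a primary-care
    hypertension registry with known ground truth, so the full pipeline and
    its parameter-recovery properties can be exercised without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
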