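Package: rxddd
Title: Drug Utilization Analytics with ATC/DDD Standardization for
    Psychiatric Inpatient Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes psychotropic prescriptions to the WHO Anatomical
    Therapeutic Chemical (ATC) classification and defined daily doses (DDD),
    computes prescribed daily doses (PDD) and PDD/DDD dose-intensity ratios
    with 95% confidence intervals, flags excessive dosing (ratio > 1.5),
    detects antipsychotic polypharmacy from temporal prescription overlap,
    screens antipsychotic orders for off-label use against ICD-10 diagnoses,
    and assembles cohort-level utilization reports (demographics by
    diagnosis, diagnosis by regimen, per-drug utilization). Includes a
    seeded synthetic inpatient-cohort generator so every analysis stage is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
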