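Package: lymphrisk
Title: Projected 30-Year Mortality Risk After Radiotherapy for Mediastinal Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Competing-risks life-table projection of 30-year absolute
    mortality risk (AMR30) from cardiovascular disease and second cancers for
    supradiaphragmatic lymphoma survivors. Combines per-patient mean organ and
    cardiac-substructure radiation doses (paired photon and proton plans),
    anthracycline exposure, smoking status, and cause-, sex- and age-specific
    background mortality rate tables into per-patient risk decompositions
    (background, chemotherapy-related and radiation-related layers), with
    dosimetric subgroup classification, direct age/sex standardization,
    paired dose-comparison statistics, and seeded synthetic-data generators
    for cohorts and Gompertz-like rate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    jsonlite,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
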