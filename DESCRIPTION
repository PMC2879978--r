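Package: reaim
Title: RE-AIM Evaluation of Multisite Weight-Management Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the five RE-AIM indices (reach, effectiveness,
    adoption, implementation, maintenance) and their composite impacts for
    multisite health-promotion programs using revised non-negative index
    formulas built on bounded standardized effect sizes: squared Cramer phi
    for contingency tables and partial eta squared from two-timepoint mixed
    ANOVA. Includes a participant/site cohort data model with delimited-file
    input and output, phase-eligibility and age-group classification, a
    calibrated synthetic-cohort generator emulating biased enrollment, skewed
    baseline measurements, phase-wise attrition and group-by-time
    differential weight change, and report builders for index, descriptive
    and completion tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    rlang,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
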