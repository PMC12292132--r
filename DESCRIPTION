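Package: growthref
Title: Fetal Growth Reference Curves by Closed-Form Polynomial Ridge Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of gestational-age growth references
    for six fetal biometric parameters (abdominal circumference, crown-rump
    length, estimated fetal weight, head circumference, biparietal diameter,
    femur length). Fits polynomial and ridge regression curves in closed form,
    derives +/-2 standard-deviation reference bands from coefficient standard
    errors, flags out-of-band measurements, validates models by 70:30 splits
    and k-fold cross-validation with residual diagnostics, and compares
    residual distributions across maternal condition groups (gestational
    diabetes, preeclampsia) with Kruskal-Wallis and Dunn rank tests. Includes
    a seeded synthetic longitudinal cohort generator with noise calibrated to
    a target coefficient of determination, so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
    dplyr,
    ggplot2,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
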