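Package: psychepi
Title: Episode-Based Analysis of New Psychiatric Admissions from Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing admission episodes from fragmented
    per-hospital psychiatric stay records in administrative claims data
    (linking inter-hospital transfers), estimating competing-risks cumulative
    incidence of discharge to the community with a from-scratch Aalen-Johansen
    estimator, fitting a harmonic Poisson model to seasonal admission counts,
    tabulating hospital- and prefecture-level discharge-rate indicators, and
    quantifying the discrepancy between the episode-based admission definition
    and a single-hospital (facility-survey style) definition. Includes a
    calibrated synthetic claims generator with known latent truth so the whole
    pipeline is testable without access to a real claims database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    cmprsk,
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
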