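Package: bgrates
Title: Background Incidence Rates of Adverse Events of Special Interest
    Across Observational Database Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising background (expected) incidence rates of
    adverse events of special interest (AESIs) in multi-database observational
    networks, as used in vaccine safety surveillance. Provides a synthetic
    patient-level data generator with known ground-truth rate structure,
    a clean-window cohort engine (calendar-year index dates, eligibility,
    recurrent events, censoring, person-time accrual), stratified incidence
    rate estimation with exact Poisson confidence intervals and small-cell
    suppression, DerSimonian-Laird random-effects pooling across databases
    with 95% prediction intervals, and classification of pooled rates into
    CIOMS adverse-event frequency categories. All user-facing functions take
    and return data frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
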