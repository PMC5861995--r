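Package: engraftr
Title: Predicting AML Xenograft Engraftment from a One-Week Ex Vivo CFSE Assay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for predicting acute myeloid leukemia (AML)
    xenograft success from a one-week ex vivo co-culture assay. Implements
    sequential flow-cytometry gating (feeder exclusion, CD45 selection,
    lymphocyte exclusion, Annexin-V/DAPI viability), the CFSE fluorescence
    dilution factor (FDF) proliferation statistic, a logistic engraftment
    classifier with an abstention zone and empirical false-discovery-rate
    threshold calibration, single-hit Poisson limiting-dilution analysis with
    profile-likelihood confidence intervals, and Kaplan-Meier / weighted
    log-rank survival stratification. Ships a synthetic-data generator that
    emulates gated flow-cytometry event tables, limiting-dilution well
    outcomes, cohort covariates and censored survival times, so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
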