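Package: calorest
Title: Bioenergetics of Caloric Restriction from Respirometry, Flux and
    Biomarker Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for sex-stratified caloric-restriction
    experiments in small mammals: converts open-flow respirometry gas traces
    into mass-specific VO2, VCO2, respiratory exchange ratio and energy
    expenditure; detects circadian extrema of those series by changepoint
    segmentation and summarises their clock times with circular statistics;
    computes mito-stress-test metrics (oxidative coupling rate, mitochondrial
    reserve capacity, glycolytic potential, metabolic potential) from
    extracellular-flux plate traces; normalises urinary biomarkers by
    creatinine and derives qPCR mtDNA/nuDNA ratios; and builds paired
    percent-change response tables with exact nonparametric contrasts,
    Dixon's Q outlier screening, correlation networks and PCA with dimension
    description. A deterministic synthetic-cohort generator reproduces a
    paired six-female/six-male design so the whole pipeline is testable
    end to end without animal data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
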