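Package: thermolyase
Title: Kinetic and Thermodynamic Characterization of Thermostable Ammonia-Lyases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the biochemical characterization of
    thermostable histidine ammonia-lyases and related enzymes. Converts raw
    spectrophotometric assay readings into molar rates via Beer-Lambert,
    fits Michaelis-Menten kinetics with turnover numbers and catalytic
    efficiencies, estimates first-order thermal-inactivation rate constants
    with half-lives, Arrhenius activation energies and Eyring
    transition-state thermodynamics, and fits two-state van't Hoff models
    to circular-dichroism thermal melts to obtain apparent melting
    temperatures. Includes seeded synthetic-data generators emulating each
    experiment type so every stage is testable without instrument data.
    All user-facing functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
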