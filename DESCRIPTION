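Package: porekin
Title: Single-Molecule Nanopore Blockade Kinetics and Transport Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-channel nanopore recordings of
    reversible analyte capture, built around polycation (PAMAM dendrimer)
    interactions with the alpha-hemolysin pore. Simulates two-state current
    traces with exponential dwell structure, Gaussian noise and low-pass
    filtering; idealizes traces into event tables via hysteresis thresholding;
    estimates capture and escape rates by censored-exponential maximum
    likelihood and bimolecular rate constants from concentration series; fits
    the voltage dependence of capture (van't Hoff-Arrhenius / Kramers forms)
    to extract effective valences, zero-voltage capture rates and barrier
    differences; converts residence times into intrapore diffusion
    coefficients through a one-dimensional drift-diffusion first-passage
    model; and computes ion-selectivity quantities (Pitzer activity
    coefficients, reversal potentials, Goldman-Hodgkin-Katz permeability
    ratios) together with Debye/Bjerrum screening lengths and
    protonation-based net-charge models.
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
    graphics,
    jsonlite,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
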