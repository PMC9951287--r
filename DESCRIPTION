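Package: porepulse
Title: Simulation and Analysis of Nanopore Resistive-Pulse Peptide Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule nanopore sensing of peptides by
    resistive-pulse analysis. Simulates ionic-current recordings with
    Poisson event arrivals, per-population Gaussian blockade levels and
    log-normal dwell times, and Bessel low-pass filtering; detects
    translocation events by a baseline-minus-five-sigma threshold rule;
    extracts dual electrical parameters (normalized blockade level and
    dwell time) per event; fits Gaussian components to blockade histograms
    and log-normal distributions to dwell times with bootstrap
    uncertainties; and decomposes mixed-sample recordings into population
    signatures with per-event assignment. Developed around the
    discrimination of fibrinopeptide A, its phosphorylated conformers and
    its N-terminal cleavage derivatives through a wild-type aerolysin pore.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
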