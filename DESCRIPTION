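Package: rtscan
Title: Information-Theoretic Scan Scheduling for Fractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential Bayesian optimal experimental design for choosing
    when (and which) tumor scans to collect during fractionated radiotherapy.
    A hybrid cellular-automaton spheroid simulator generates high-fidelity
    tumor and necrotic volume time series; low-fidelity one- and
    two-compartment logistic growth models with impulsive linear-quadratic
    radiation kill are calibrated against accumulated scans by delayed-
    rejection adaptive Metropolis sampling; each new scan day is chosen to
    maximize a k-nearest-neighbor estimate of the mutual information between
    the radiosensitivity parameter and the candidate measurement, optionally
    penalized for skipping intermediate days.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
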