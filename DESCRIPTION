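Package: cestfold
Title: Multi-State Chemical Exchange Analysis of CEST NMR Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and global fitting of chemical exchange
    saturation transfer (CEST) NMR profiles under two- to four-state
    chemical exchange, built around the Bloch-McConnell equations.
    Extracts chemical shifts, populations and exchange rates of sparsely
    populated ("invisible") protein states such as folding intermediates,
    computes residue-level composite chemical-shift perturbation
    statistics, and converts denaturant-dependent populations and rates
    into free energies and urea m-values for ground and transition
    states.  Includes a seeded synthetic-data generator so every stage of
    the pipeline can be exercised and validated without spectrometer
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
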