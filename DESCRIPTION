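Package: envstates
Title: Transient Electrophysiological Network States from Amplitude Envelopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Segments multichannel electrophysiological recordings into
    recurring transient network states. Band-limited signals are leakage
    corrected by symmetric orthogonalization, converted to Hilbert amplitude
    envelopes, downsampled and concatenated across subjects, and modeled with
    a K-state Gaussian-observation hidden Markov model fitted by
    expectation-maximization with multiple restarts and decoded by the Viterbi
    algorithm. Provides temporal state metrics (fractional occupancy,
    fractional count, mean lifetime, transition matrices, sliding-window
    occurrence rates), GLM partial-correlation state maps (including collapsed
    multi-state designs, narrow-band and ultra-slow variants),
    permutation-based group comparison with threshold-free cluster enhancement
    for family-wise error control, and a ground-truthed synthetic-cohort
    generator with spectrally matched stationary surrogates for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
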