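Package: fretkin
Title: Single-Molecule FRET Trace Simulation, Idealization and Dwell-Time Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of two-channel (donor/acceptor)
    single-molecule FRET intensity time traces of the kind produced by
    surface-tethered SNARE-complex disassembly assays. Provides a
    continuous-time Markov simulator of conformational dynamics with
    stochastic dye labeling, photobleaching and channel cross-talk; linear
    leakage unmixing and FRET efficiency computation; photobleach-aware trace
    sectioning and classification; per-molecule Gaussian-emission hidden
    Markov model idealization (Baum-Welch and Viterbi); dwell-time extraction,
    short/long-lived population partitioning on a log timescale and
    exponential rate fitting; and equilibrium binding-isotherm and
    competition-assay arithmetic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    arrow,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
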