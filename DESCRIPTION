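Package: xplodeR
Title: Coulomb-Explosion Fragmentation Analysis of Protonated Cystine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates surrogate Coulomb-explosion trajectory ensembles of the
    triply charged protonated cystine ion and analyses them with a per-bond
    integrity parameter referenced to thermalized bond-length baselines.
    Detects bond breaking, tabulates ensemble break probabilities with
    confidence intervals, identifies fragments from the molecular graph and
    assigns monoisotopic, average and nominal m/z values. Also provides the
    ion-yield spectroscopy layer used to interpret such experiments:
    square-root-law time-of-flight calibration, peak integration, partial and
    summed ion yields over a photon-energy scan, and Gaussian broadening of
    computed stick spectra.
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
    igraph,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
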