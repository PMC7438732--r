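Package: ppasekin
Title: Allosteric Kinetics of Membrane-Bound Pyrophosphatases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for substrate-saturation kinetics of
    membrane-bound inorganic pyrophosphatases (H+-PPases and Na+-PPases)
    assayed with magnesium-pyrophosphate as substrate. Computes the
    equilibrium speciation of pyrophosphate among its H+, Mg2+, K+ and Na+
    complexes to obtain the true substrate concentration [Mg2PPi], evaluates
    the empirical Hill equation and a two-state concerted (MWC-type)
    allosteric rate law, fits either model to replicate assay rates by
    1/variance-weighted nonlinear least squares with asymptotic standard
    errors, summarises sodium sensitivity as percent decreases of the
    maximal rate, and generates synthetic replicate assay datasets that
    emulate the matched-magnesium and fixed-magnesium experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
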