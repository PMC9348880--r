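Package: specklematch
Title: Matching Two-Time X-Ray Speckle Correlation Maps to Phase-Field
    Simulations of Protein Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying two-time correlation (TTC) maps from
    X-ray photon correlation spectroscopy (XPCS) of phase-separating
    protein solutions. Integrates the two-dimensional Cahn-Hilliard
    equation with a concentration-dependent mobility that models
    gelation-induced dynamical arrest, converts order-parameter fields to
    coherent speckle intensities and two-time correlation maps per
    scattering ring, compresses preprocessed maps to 32-dimensional
    latent vectors with a convolutional auto-encoder trained on
    simulations, and matches experimental (or pseudo-experimental) maps
    to the simulation library by differential evolution over the quench
    depth, gelation point and time/Q calibration parameters. Fitted
    parameters are placed on a Landau phase diagram together with the
    binodal, spinodal and estimated gel line.
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
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
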