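Package: pelletpulse
Title: Diffusion-Adsorption Modelling of Phosphorus Release from a Fertilizer Pellet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the release of dissolved phosphorus from a fertilizer
    pellet into a saturated one-dimensional soil column and its first-order
    exchange with the adsorbed pool, emulates in-situ sampling of the column by
    microdialysis probes or suction cups (sampling schedules, recovery
    calibration, replicate noise), and estimates the transport parameters
    (effective diffusivity, adsorption and desorption rates, and the initial
    pulse shape) from probe time series by weighted least squares. Includes a
    cosine-spectral reference solution for solver verification, a synthetic
    experiment generator for parameter-recovery studies, tidy exporters and
    ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
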