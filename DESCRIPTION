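Package: minflux
Title: Thermodynamics of the Reversible MinDE Reaction-Diffusion Oscillator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pole-to-pole Min protein oscillations in a rod-shaped
    bacterial cell using a microscopically reversible reaction-diffusion
    model on a 2D axisymmetric finite-volume mesh, and accounts for the
    nonequilibrium free-energy dissipation of every reaction step and of
    cytoplasmic diffusion. Provides oscillation detection, period
    estimation, a mid-cell-marking performance score, bifurcation
    localization along rate-constant axes, parameter-plane scans, and
    constrained free-energy-allocation (dissipation strategy) searches at
    a fixed ATP budget.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
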