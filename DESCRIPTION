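Package: cleftflow
Title: Standing-Gradient Water and Electrolyte Transport in Epithelial Clefts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state water and electrolyte transport through the
    lateral intercellular cleft of a leaky absorbing epithelium using a
    standing-gradient model with tight-junction water flux, uniformly
    distributed ion pumps, and aquaporin-mediated lateral water influx. The
    nonlinear convection-diffusion boundary-value problem is solved by a
    damped-Newton relaxation scheme and, independently, by a shooting method;
    closed-form scales (homogeneous concentration, inhomogeneity length) and
    non-perturbative long- and short-cleft approximations are provided, along
    with tidy parameter sweeps, flux summaries, and plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
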