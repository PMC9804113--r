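Package: predimm
Title: Predictive-Coding Model of T Cell Memory and Antigen Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a nonlinear ODE/DDE model of conventional and regulatory
    T cell population dynamics in which both populations act as predictive-coding
    units: conventional T cells predict antigen concentration, regulatory T cells
    predict the excess immune response, and their rectified prediction errors
    drive the formation of long-lived memory compartments. Provides composable
    piecewise antigen input protocols (constant, saturating-exponential,
    multi-phase immunotherapy schedules), steady-state detection, parameter and
    protocol sweeps with threshold localisation, phase diagrams, allergen
    immunotherapy and persistence experiments, a one-at-a-time parameter
    sensitivity analysis, and a command-line interface. Includes a constant-delay
    extension for delayed memory formation and linear, sigmoidal and step-like
    dose-response variants of T cell activation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    yaml,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
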