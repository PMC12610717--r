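Package: tgakin
Title: Kinetic Analysis and Prediction of Multi-Step Thermal Decomposition from Thermogravimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for solid-state decomposition kinetics from thermogravimetric
    (TGA) mass-loss curves. Implements a consecutive three-step reaction scheme
    (A -> B -> C -> D) with autocatalytic Sestak-Berggren rate functions,
    activation-energy determination by the Kissinger method (including a
    quadratic extension yielding temperature-dependent activation energies from
    curved Kissinger plots), per-curve nonlinear least-squares fitting with
    fixed activation energies (single-curve multivariate kinetic analysis), and
    extrapolation of fitted kinetics to processing protocols such as isothermal
    holds with or without a preceding heating ramp. A synthetic-data generator
    emulates a multi-heating-rate study design for closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
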