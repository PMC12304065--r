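Package: phenomoments
Title: Moment Reduction of Phenotype-Structured Models of Cancer Adaptive Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to reduce nonlocal phenotype-structured
    reaction-advection-diffusion equations, as used to model the adaptive
    dynamics of cancer cell populations, to closed systems of ordinary
    differential equations for the population size and the first N moments
    of the phenotypic distribution. Provides a generic moment-equation
    assembler for arbitrary moment order N and Taylor truncation order M
    with Gaussian and truncation closures, a reference finite-difference
    solver for the full partial differential equation (explicit time
    stepping, upwind advection, central diffusion, conservative no-flux
    boundaries), constructors for quadratic-selection, Hill/tanh and
    fitness-generating-function (G-function) models, and an adaptive-therapy
    simulator with hysteresis treatment control, time-to-progression and
    cumulative-dose summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
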