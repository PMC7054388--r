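Package: gctwoclone
Title: Two-Clone Germinal Center Dynamics and Plasma Cell Regime Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulator for a germinal center seeded by two
    B-cell clones -- one broadly reactive, receiving survival signals from two
    T follicular helper (Tfh) cell families, and one strain-specific, served
    by a single family -- competing for a limited, non-renewing Tfh pool while
    advancing through stages of productive somatic hypermutation. Provides the
    stage-structured ODE right-hand side, adaptive integration with
    germinal-center termination detection, a fixed-step Runge-Kutta reference
    integrator for cross-validation, outcome classification (monoclonal versus
    biclonal plasma output), parameter sweeps over the broadly reactive
    selection rate, seeding bias, and forward-mutation probability, and
    bisection search for the regime boundaries between plasma-cell outcomes.
    Includes a YAML/JSON configuration layer and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
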