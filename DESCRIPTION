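Package: lvimm
Title: Immigration-Stabilized Lotka-Volterra Predator-Prey Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how small immigration (or emigration) terms
    alter the stability of two-species Lotka-Volterra predator-prey dynamics
    under Holling type I, II and III functional responses. Provides the
    modified vector fields with constant and density-dependent immigration,
    closed-form coexistence equilibria for the type I immigration cases,
    numerical equilibrium solving with residual certification for the
    saturating responses, analytic Jacobians with trace/determinant stability
    classification, closed-form amplitude decay rates, an adaptive
    Dormand-Prince integrator with positivity guards, ensembles driven by
    piecewise-constant random immigration pulses, envelope-based decay-rate
    estimation from trajectories, and a scenario suite that checks the full
    stability matrix across response types and immigration modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
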