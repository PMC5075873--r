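Package: statevar
Title: Variation of State and Robustness in Perturbed Biological Network Models
Version: 0.1.0
Authors@R: person("statevar", "Maintainers", email = "statevar@example.org",
    role = c("aut", "cre"))
Description: Quantifies the variation of state (Shannon entropy of discretized
    system-state trajectories, in bits) and robustness (fraction of module
    states unchanged by perturbation) of biological network models before and
    after an external stimulus.  Includes a kinetic (Michaelis-Menten) ODE
    engine for condition-specific metabolic models with linear interpolation
    between condition parameter sets, a synchronous Boolean simulator for
    signed module-level transcriptional networks with step-function inputs and
    clamped modules, exhaustive perturbation designs, calibration of maximum
    velocities to metabolite time courses, the associated rank-sum, proportion
    and binomial tests, seeded synthetic-data generators for all inputs, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
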