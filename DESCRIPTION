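Package: reelinsink
Title: Kinetics of Intraneuronal Amyloid-Beta Sequestration by Reelin
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of intraneuronal amyloid-beta 42
    (Abeta42) sequestration by the glycoprotein reelin and its downstream
    inhibition of GSK3beta, in high-reelin entorhinal layer II neurons versus
    low-reelin cortical neurons. Provides the four-variable mass-action ODE
    system, its closed-form steady states, Jacobian-based linear stability
    analysis, stiff time-course integration under piecewise-constant
    infection-like Abeta production schedules, genotype perturbations
    (protective RELN variant, ApoE e4/e4), an exhaustive steady-state grid
    search that fits an Abeta production fold change and a reelin-knockdown
    fraction to observed densitometry mean-ratio pairs, and a synthetic
    per-cell fluorescence-densitometry generator for end-to-end testing of
    the ratio-of-means estimator and the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
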