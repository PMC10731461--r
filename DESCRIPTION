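Package: by2growth
Title: Monod-Type Growth and Nutrient-Uptake Models for Tobacco BY-2
    Suspension Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, calibration and optimization toolkit for
    unstructured segregated Monod-type models of tobacco BY-2 cell
    suspension cultures in stirred-tank bioreactors. Provides two model
    variants (an initial sucrose-driven model and an improved model with
    sucrose hydrolysis into glucose and fructose), a batch/semi-continuous
    process simulator with feed control and periodic drains, weighted
    least-squares parameter identification under inhibition-constant
    constraints with residual-bootstrap confidence intervals, K-fold
    cross-validation for model comparison, and bi-criteria (biomass yield
    versus process time) Pareto optimization over initial dry mass and
    sucrose. A synthetic-data generator with constant-plus-proportional
    measurement noise makes every analysis reproducible without
    bioreactor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
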