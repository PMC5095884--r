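Package: lumigrow
Title: Tumor Growth Kinetics from Bioluminescence Imaging by Nonlinear
    Mixed-Effects Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits a two-compartment (proliferative/necrotic) logistic tumor
    growth model to longitudinal bioluminescence imaging data from mouse
    cohorts using a stochastic approximation EM (SAEM) nonlinear
    mixed-effects engine with lognormal inter-animal variability and a
    proportional residual error model. Includes cells-to-light calibration
    by regression through the origin, conversion between photon flux and
    tumor volume, sequential estimation of the caliper-volume
    proportionality constant and the implied stromal fraction, a synthetic
    cohort generator for parameter-recovery studies, and an end-to-end
    analysis pipeline producing parameter tables with inter-animal CVs and
    relative standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
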