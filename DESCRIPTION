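Package: fhnlif
Title: Leaky Integrate-and-Fire Reduction of the Stochastic FitzHugh-Nagumo Neuron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the stochastic FitzHugh-Nagumo neuron in the
    excitable regime and reducing it to an embedded leaky integrate-and-fire
    (LIF) model. Provides the closed-form equilibrium and eigenstructure
    analysis of the deterministic model, Stratonovich integration of the
    stochastic system with spike detection and interspike-interval (ISI)
    sampling, linearization around the stable focus with pathwise error-scaling
    experiments under common noise, the rotation normal form and its averaged
    radial Ornstein-Uhlenbeck approximations, Monte-Carlo calibration of a
    sigmoidal conditional firing probability, hazard-rate ISI density
    estimation, and Welch power-spectral-density comparisons between the full,
    linearized and radial processes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
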