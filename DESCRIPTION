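Package: helibimod
Title: Binormality and Bimodality Analysis of B-DNA Base-Pair-Step Helical Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical detection of binormality and bimodality in the
    distributions of the six inter-base-pair helical parameters (shift, slide,
    rise, tilt, roll, twist) of B-DNA base-pair steps. Fits one- and
    two-component Gaussian models by maximum likelihood, selects between them
    with the Bayesian Information Criterion and a Bayes-factor posterior
    probability, and classifies the modality of binormal fits with the
    generalized Helguero separation criterion. Also provides a two-state
    bimodal extension of the harmonic elastic model of base-pair-step
    deformations (stiffness matrices from inverse covariances, smooth
    two-branch energy surfaces), transition-kinetics analysis of two-state
    time series, and seeded synthetic-data generators (binormal ensembles,
    telegraph time series with Gaussian emissions, correlated harmonic
    ensembles) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
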