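Package: moosespr
Title: Statistical Population Reconstruction of Northeastern Minnesota Moose
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Integrated population modelling for the northeastern Minnesota
    moose (Alces alces) population, 2005-2020. Combines aerial-survey class
    counts (calves, adult females, adult males) with telemetry mortality
    counts from collared adults in a minimum chi-square statistical
    population reconstruction, yielding annual abundance, recruitment and
    adult survival with inverse-Hessian standard errors inflated by a
    goodness-of-fit scale factor. Includes a perturbation sensitivity
    analysis of the 2009-2013 decline, AR(1) vital-rate forecasting with a
    stochastic ten-year cohort projection, and a synthetic-data generator
    for simulation studies of estimator performance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
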