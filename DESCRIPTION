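Package: oefsim
Title: Organism-Environment Feedback, Hysteresis and Dynamic Regimes Under
    Ramped Environmental Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the strength of organism-environment feedback
    shapes ecosystem responses to a slowly ramped environmental driver. The
    package implements a minimal one-dimensional ecosystem model with a
    sigmoidal self-replacement feedback, forced simulations under triangular
    driver ramps, equilibrium and bistability analysis including the critical
    feedback exponent at which alternative stable states appear; absolute
    nonlinearity (root-mean-square difference between penalized-spline and
    straight-line fits) and hysteresis (mean absolute up-down difference at
    matched driver levels) response statistics; a seeded stochastic generator
    that emulates a temperature-ramped predator-prey-bacteria microcosm
    experiment with treatment-dependent oxygen exchange; and dynamic-regime
    detection from time series via dynamic time warping distances, Ward
    hierarchical clustering, likelihood-ratio tests of cluster-treatment
    association, and ANOVA/ANCOVA comparisons of the response metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
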