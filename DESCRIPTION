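Package: mmsmooth
Title: Multiple-Membership Multilevel Smoothing for Small-Area Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk-adjusts small-area hospitalization counts and smooths the
    resulting rates with Poisson multilevel multiple-membership models. Each
    area (municipality) carries an unstructured heterogeneity random effect
    and a spatially structured effect formed as the weighted sum of the
    effects of all areas within a chosen distance radius; an optional third
    random effect represents an administrative level (health district) or an
    environmental-risk zone. The package provides indirect standardization
    via a logistic risk-adjustment model with a concordance (c-)statistic,
    Laplace-approximated marginal maximum-likelihood estimation of the
    variance components, per-municipality variance decomposition including
    the spatially structured variability quota, empirical-Bayes smoothed
    risk-adjusted rates, quintile choropleth classification and export, and a
    synthetic-data generator that emulates the skewed municipality structure
    the models are designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
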