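Package: salmosync
Title: Dynamic Factor Analysis of Spatial Synchrony in Atlantic Salmon
    Body Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify spatial synchrony in annual mean fork
    length of Atlantic salmon (Salmo salar) across rivers.  Implements
    dynamic factor analysis (DFA) for multivariate time series with
    missing observations: latent random-walk trends estimated by an EM
    algorithm with a Kalman smoother, structured observation-error
    covariances, AICc model selection, varimax rotation, and annual
    covariate effects.  Also builds the marine covariates used in such
    analyses: thermal-habitat area indices from gridded sea surface
    temperature and sea-ice fields via a piecewise-linear growth
    potential curve, a food-availability index from principal
    components of prey biomass, density indices from pre-fishery
    abundance with mortality back-adjustment, and fishery exploitation
    rates.  A synthetic-data module generates fork-length panels from a
    known DFA truth, gridded ocean fields, and autocorrelated covariate
    series so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
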