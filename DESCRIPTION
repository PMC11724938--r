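Package: mifs
Title: Multiple Imputation with Longitudinal Factor Scores for Intensive
    Longitudinal Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for handling nonignorable missingness in intensive
    longitudinal data when the missingness is driven by latent factors.
    Implements a linear Gaussian state-space / process factor analysis
    core (simulation, Kalman filtering, fixed-interval smoothing, and
    maximum likelihood estimation by prediction error decomposition),
    chained-equations multiple imputation with predictive mean matching
    that augments the imputation model with longitudinal factor scores,
    lagged variables and missingness indicators, four missing-data
    handling pipelines (listwise deletion, MI on manifest variables,
    partial MI, and MI with factor scores), Rubin's-rules pooling, and a
    Monte Carlo evaluation harness with bias, RMSE, power and coverage
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
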