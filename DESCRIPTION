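Package: salmonregimes
Title: Bayesian Multivariate State-Space Models of Salmonid Productivity Regimes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect and attribute nonstationary productivity regimes in
    communities of anadromous salmonids from brood-year stock-recruitment time
    series. Implements a Bayesian multivariate autoregressive state-space (MARSS)
    model with a time-varying Ricker intercept (intrinsic productivity as a
    correlated multivariate random walk), environmental covariate effects, and
    full observation/process covariance matrices, fitted by a conjugate Gibbs
    sampler with forward-filter backward-sampling. Includes an integrated
    Steelhead life-cycle submodel (logit marine survival, adult returns, and run
    timing as linked random-walk regressions), covariate construction utilities
    (age-structure brood-year lagging, cumulative logging windows, seal exposure,
    PCA collapsing of collinear ocean indices, variance inflation factors),
    dynamic factor analysis for missing-data imputation, convergence diagnostics,
    Pareto-smoothed importance-sampling leave-one-out model comparison, posterior
    predictive checks, regime summaries, and a synthetic data generator that
    emulates a small coastal watershed monitored for forty years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
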