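Package: divepop
Title: From Dive Signals to Population Dynamics for a Front-Foraging Seabird
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking biologging dive records, prey-capture inference,
    ocean-front indices and Bayesian state-space population dynamics for a
    front-foraging marine predator (the king penguin as the motivating case).
    Includes seeded synthetic-data generators with attached ground truth;
    dive, wiggle, step, bout and oesophageal feeding-event detection;
    negative-binomial modelling of bout-level prey captures with all-subsets
    QAIC model averaging and concordance-index validation; Poisson log-linear
    imputation of missing colony counts and a Gibbs/forward-filter
    backward-sampler for the stochastic Gompertz state-space model with
    density dependence and an environmental covariate; gridded sea-surface
    temperature products (anomalies, box-mean anomalies, 5 degree C isotherm
    front location, leading-EOF dipole index); and a penalized
    cubic-regression-spline GAM for breeding success.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    mgcv,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    geosphere
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
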