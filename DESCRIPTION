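Package: smokedyn
Title: System-Dynamics Modelling of Population Smoking Behaviour and
    Nicotine Dependence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A three-stock system-dynamics model of smoking behaviour
    (less-dependent smokers, heavily dependent smokers, former smokers)
    for studying how tobacco-control-induced changes in per-capita rates
    of initiation, progression, cessation and relapse affect the
    proportion of smokers who are heavily dependent (the "hardening
    hypothesis"). Provides the deterministic model with exponentially
    trending rates and its analytic equilibrium, step-change perturbation
    experiments, an overdispersed-Poisson observation model linking the
    trajectory to survey count series, Bayesian calibration by adaptive
    Markov chain Monte Carlo with convergence diagnostics and
    posterior-predictive trajectory bands, and a synthetic survey
    generator with a parameter-recovery experiment driver so the full
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
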