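# Baseline parameter set used across tests (the package defaults: constant
# total population, all trend rates zero).
baseline_params <- function(...) smoking_params(...)

# Random valid parameter set with constant rates and positive initiation,
# for property-style checks.
random_constant_params <- function() {
  P0 <- 1e6
  fr <- stats::runif(3, 0.02, 0.25)  # stock fractions of P0
  smoking_params(
    P0 = P0,
    L0 = fr[1] * P0, H0 = fr[2] * P0, F0 = fr[3] * P0,
    mu = stats::runif(1, 0.005, 0.05),
    zeta = stats::runif(1, 1.1, 3),
    eta = stats::runif(1, 0, 0.9),
    lam = stats::runif(1, 0.1, 0.9),
    u0 = stats::runif(1, 0.005, 0.05),
    v0 = stats::runif(1, 0.05, 0.5),
    c0 = stats::runif(1, 0.1, 0.8),
    r0 = stats::runif(1, 0.05, 0.5))
}

# A tiny valid survey data set for interface-level tests.
tiny_survey <- function() {
  data.frame(
    year = c(2001, 2004, 2001, 2004),
    kind = rep(c("current_smokers", "former_smokers"), each = 2),
    count = c(230000L, 210000L, 250000L, 260000L))
}
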