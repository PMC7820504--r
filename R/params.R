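#' Model parameters for the three-stock smoking model
#'
#' Constructs and validates the full parameter set of the smoking
#' system-dynamics model: initial stocks, mortality and cessation ratios,
#' initial per-capita behaviour-change rates, and the fractional trend
#' rates that make those per-capita rates grow or decay exponentially in
#' time. Defaults are the baseline parameterization used throughout the
#' simulation experiments (constant total population, all trends zero).
#'
#' The model tracks three stocks in a total population `P`: less-dependent
#' smokers `L`, heavily dependent smokers `H`, and former smokers `F`.
#' Never smokers are the residual `N = P - L - H - F`. Per-capita mortality
#' is `mu` for less-dependent smokers, `zeta * mu` (with `zeta > 1`) for
#' heavily dependent smokers and `eta * mu` (with `eta < 1`) for former
#' smokers. Cessation rates are `c` for less-dependent and `lam * c`
#' (with `0 < lam < 1`) for heavily dependent smokers.
#'
#' @param P0 initial total population (persons).
#' @param L0,H0,F0 initial stocks of less-dependent smokers, heavily
#'   dependent smokers and former smokers (persons).
#' @param mu per-capita mortality rate of less-dependent smokers (1/year).
#' @param zeta mortality-rate ratio for heavily dependent smokers
#'   (dimensionless, `> 1`).
#' @param eta mortality-rate ratio for former smokers (dimensionless,
#'   `0 <= eta < 1`).
#' @param lam cessation-rate ratio for heavily dependent smokers
#'   (dimensionless, `0 < lam < 1`).
#' @param u0 initial per-capita initiation rate (1/year).
#' @param v0 initial per-capita rate of progression to heavily dependent
#'   smoking (1/year).
#' @param c0 initial per-capita cessation rate for less-dependent smokers
#'   (1/year).
#' @param r0 initial per-capita relapse rate (1/year).
#' @param g0 initial fractional population growth rate (1/year).
#' @param delta_u,delta_v,delta_c,delta_r fractional rates of increase of
#'   `u`, `v`, `c`, `r` per year (may be negative, giving exponential
#'   decay of the rate).
#' @param delta_g fractional rate of *decrease* of the population growth
#'   rate `g` per year, so `g(t) = g0 * exp(-delta_g * t)`.
#'
#' @return An object of class `smoking_params`: a named list of validated
#'   parameter values.
#' @examples
#' p <- smoking_params()
#' equilibrium_q(p)  # 0.5128...
#' @export
smoking_params <- function(P0 = 1e6,
                           L0 = 4e4, H0 = 6e4, F0 = 1.5e5,
                           mu = 0.02, zeta = 1.5, eta = 0.5, lam = 0.4,
                           u0 = 0.01, v0 = 0.2, c0 = 0.4, r0 = 0.2,
                           g0 = 0,
                           delta_u = 0, delta_v = 0, delta_c = 0,
                           delta_r = 0, delta_g = 0) {
  p <- list(P0 = P0, L0 = L0, H0 = H0, F0 = F0,
            mu = mu, zeta = zeta, eta = eta, lam = lam,
            u0 = u0, v0 = v0, c0 = c0, r0 = r0, g0 = g0,
            delta_u = delta_u, delta_v = delta_v, delta_c = delta_c,
            delta_r = delta_r, delta_g = delta_g)
  validate_smoking_params(p)
  structure(p, class = "smoking_params")
}

#' Validate a smoking-model parameter set
#'
#' Checks the structural assumptions of the model: nonnegative stocks that
#' fit inside the initial population, nonnegative rates, `zeta > 1`,
#' `0 <= eta < 1` and `0 < lam < 1`.
#'
#' @param p a list or `smoking_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_smoking_params <- function(p) {
  need <- c("P0", "L0", "H0", "F0", "mu", "zeta", "eta", "lam",
            "u0", "v0", "c0", "r0", "g0",
            "delta_u", "delta_v", "delta_c", "delta_r", "delta_g")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameters: ", paste(miss, collapse = ", "))
  bad <- vapply(p[need], function(x)
    !is.numeric(x) || length(x) != 1L || !is.finite(x), logical(1))
  if (any(bad))
    stop("non-finite or non-scalar parameters: ",
         paste(need[bad], collapse = ", "))
  if (p$P0 <= 0) stop("P0 must be positive")
  if (p$L0 < 0 || p$H0 < 0 || p$F0 < 0)
    stop("initial stocks L0, H0, F0 must be nonnegative")
  if (p$L0 + p$H0 + p$F0 > p$P0)
    stop("initial stocks exceed the total population (L0 + H0 + F0 > P0)")
  if (p$mu < 0 || p$u0 < 0 || p$v0 < 0 || p$c0 < 0 || p$r0 < 0)
    stop("rates mu, u0, v0, c0, r0 must be nonnegative")
  if (p$zeta <= 1) stop("zeta must exceed 1 (heavy smokers die faster)")
  if (p$eta < 0 || p$eta >= 1) stop("eta must lie in [0, 1)")
  if (p$lam <= 0 || p$lam >= 1) stop("lam must lie in (0, 1)")
  invisible(p)
}

#' @export
print.smoking_params <- function(x, ...) {
  cat("<smoking_params>\n")
  cat(sprintf("  population: P0 = %g (L0 = %g, H0 = %g, F0 = %g)\n",
              x$P0, x$L0, x$H0, x$F0))
  cat(sprintf("  mortality:  mu = %g, zeta = %g, eta = %g\n",
              x$mu, x$zeta, x$eta))
  cat(sprintf("  behaviour:  u0 = %g, v0 = %g, c0 = %g, r0 = %g, lam = %g\n",
              x$u0, x$v0, x$c0, x$r0, x$lam))
  cat(sprintf("  trends:     delta_u = %g, delta_v = %g, delta_c = %g, delta_r = %g\n",
              x$delta_u, x$delta_v, x$delta_c, x$delta_r))
  cat(sprintf("  growth:     g0 = %g, delta_g = %g\n", x$g0, x$delta_g))
  invisible(x)
}

# keys used in flat config files (lower-case Table-style symbol names)
.config_keys <- c(p0 = "P0", l0 = "L0", h0 = "H0", f0 = "F0",
                  mu = "mu", zeta = "zeta", eta = "eta", lam = "lam",
                  u0 = "u0", v0 = "v0", c0 = "c0", r0 = "r0", g0 = "g0",
                  delta_u = "delta_u", delta_v = "delta_v",
                  delta_c = "delta_c", delta_r = "delta_r",
                  delta_g = "delta_g")

#' Read model parameters from a flat YAML or JSON config file
#'
#' The file is a flat key-value mapping using the conventional symbol
#' names `p0, g0, delta_g, l0, h0, f0, mu, zeta, eta, lam, u0, v0, c0,
#' r0, delta_u, delta_v, delta_c, delta_r`. Keys are case-insensitive;
#' missing keys fall back to the package defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated [smoking_params()] object.
#' @export
read_smoking_params <- function(path) {
  raw <- yaml::read_yaml(path)  # YAML is a superset of JSON
  if (!is.list(raw)) stop("config must be a flat key-value mapping")
  names(raw) <- tolower(names(raw))
  unknown <- setdiff(names(raw), names(.config_keys))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- stats::setNames(raw, .config_keys[names(raw)])
  do.call(smoking_params, args)
}

#' Write model parameters to a flat YAML config file
#'
#' @param p a [smoking_params()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smoking_params <- function(p, path) {
  validate_smoking_params(p)
  out <- stats::setNames(unclass(p)[.config_keys], names(.config_keys))
  yaml::write_yaml(out, path)
  invisible(path)
}
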