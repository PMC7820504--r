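#' Evaluate an exponentially trending per-capita rate
#'
#' Per-capita behaviour-change rates trend exponentially: a rate with base
#' value `base` and fractional rate of increase `delta` per year equals
#' `base * exp(delta * t)` at time `t`. A negative `delta` gives decay.
#'
#' @param base base value of the rate at `t = 0` (1/year).
#' @param delta fractional rate of increase per year (may be negative).
#' @param t time in years. Vectorised.
#' @return The rate value(s) at `t`.
#' @examples
#' rate_at_time(0.4, 0, 10)      # constant rate
#' rate_at_time(0.01, -0.1, 10)  # 0.01 * exp(-1)
#' @export
rate_at_time <- function(base, delta, t) {
  base * exp(delta * t)
}

# population growth rate decays as g0 * exp(-delta_g * t)
growth_rate_at_time <- function(g0, delta_g, t) {
  g0 * exp(-delta_g * t)
}

#' Instantaneous rates of change of the model stocks
#'
#' Evaluates the flow balance of the three-stock model at a given state
#' and time. Initiation adds `u * N` persons/year to less-dependent
#' smokers (`N = P - L - H - F` never smokers); progression moves `v * L`
#' to heavy dependence; cessation removes `c * L` and `lam * c * H` into
#' former smokers; relapse returns `r * F` to the less-dependent stock;
#' mortality removes `mu * L`, `zeta * mu * H` and `eta * mu * F`; the
#' total population grows as `g * P`.
#'
#' @param state named list or vector with elements `L`, `H`, `F`, `P`
#'   (persons).
#' @param params a [smoking_params()] object.
#' @param t time in years (rates are evaluated at `t` via
#'   [rate_at_time()]).
#' @return Named numeric vector `c(L=, H=, F=, P=)` of derivatives in
#'   persons/year.
#' @examples
#' p <- smoking_params()
#' smoking_derivatives(list(L = 4e4, H = 6e4, F = 1.5e5, P = 1e6), p, 0)
#' @export
smoking_derivatives <- function(state, params, t = 0) {
  validate_smoking_params(params)
  s <- as.list(state)
  L <- s$L; H <- s$H; F <- s$F; P <- s$P
  if (any(!is.finite(c(L, H, F, P))))
    stop("state must contain finite L, H, F, P")
  if (L < 0 || H < 0 || F < 0)
    stop("invalid state: negative stock")
  if (P - L - H - F < 0)
    stop("invalid state: never-smoker residual N = P - L - H - F is negative")
  u <- rate_at_time(params$u0, params$delta_u, t)
  v <- rate_at_time(params$v0, params$delta_v, t)
  cc <- rate_at_time(params$c0, params$delta_c, t)
  r <- rate_at_time(params$r0, params$delta_r, t)
  g <- growth_rate_at_time(params$g0, params$delta_g, t)
  N <- P - L - H - F
  c(L = u * N + r * F - (v + cc + params$mu) * L,
    H = v * L - (params$lam * cc + params$zeta * params$mu) * H,
    F = cc * L + params$lam * cc * H - (r + params$eta * params$mu) * F,
    P = g * P)
}

# RHS in deSolve form; state y = (L, H, F, P, Q), Q = cumulative quit flow
smoking_rhs <- function(t, y, params) {
  p <- params
  u <- p$u0 * exp(p$delta_u * t)
  v <- p$v0 * exp(p$delta_v * t)
  cc <- p$c0 * exp(p$delta_c * t)
  r <- p$r0 * exp(p$delta_r * t)
  g <- p$g0 * exp(-p$delta_g * t)
  L <- y[1L]; H <- y[2L]; F <- y[3L]; P <- y[4L]
  N <- P - L - H - F
  quit <- cc * L + p$lam * cc * H
  list(c(u * N + r * F - (v + cc + p$mu) * L,
         v * L - (p$lam * cc + p$zeta * p$mu) * H,
         quit - (r + p$eta * p$mu) * F,
         g * P,
         quit))
}

# flatten params for the compiled fixed-step integrator
.pvec <- function(p) {
  c(p$mu, p$zeta, p$eta, p$lam, p$u0, p$v0, p$c0, p$r0, p$g0,
    p$delta_u, p$delta_v, p$delta_c, p$delta_r, p$delta_g)
}

.init_state <- function(p) c(p$L0, p$H0, p$F0, p$P0, 0)

# fast trajectory at arbitrary (sorted) times via the compiled RK4 path;
# returns the raw L,H,F,P,Q matrix. Used by the inference hot loop.
integrate_states <- function(params, times, hmax = 0.025) {
  .integrate_states_cpp(.pvec(params), .init_state(params), times, hmax)
}

# derived columns shared by both integration routes
trajectory_frame <- function(times, states, params) {
  L <- states[, 1L]; H <- states[, 2L]; F <- states[, 3L]
  P <- states[, 4L]; Q <- states[, 5L]
  cur <- L + H
  cc <- rate_at_time(params$c0, params$delta_c, times)
  q <- ifelse(cur > 0, H / cur, NA_real_)
  percap <- ifelse(cur > 0, (cc * L + params$lam * cc * H) / cur, NA_real_)
  out <- data.frame(t = times, L = L, H = H, F = F, P = P,
                    N = P - L - H - F,
                    current_prev = cur / P, past_prev = F / P,
                    q = q, percap_cess = percap, Qcum = Q)
  structure(out, class = c("smoking_trajectory", "data.frame"),
            params = params)
}

#' Simulate the smoking model
#'
#' Numerically integrates the model from its initial state (anchored at
#' `t = 0`) and returns the trajectory on a uniform time grid together
#' with the derived outputs: current smoking prevalence `(L+H)/P`, past
#' smoking prevalence `F/P`, the heavy-dependence fraction
#' `q = H/(L+H)`, the per-capita cessation rate
#' `(cL + lam*c*H)/(L+H)`, and the cumulative successful-quit flow `Qcum`
#' (used for past-year-quitter observables). Integration uses the
#' adaptive `lsoda` solver with relative tolerance `1e-8` and absolute
#' tolerance `1e-6` persons; time-varying rates are evaluated
#' continuously inside the solver.
#'
#' A negative `from` extends the trajectory before the initial condition
#' (the model is integrated backwards from `t = 0`); this covers trailing
#' observation windows that begin before the first survey.
#'
#' @param params a [smoking_params()] object.
#' @param horizon simulation length in years (`> 0`), measured from
#'   `from`.
#' @param grid_step output grid spacing in years (`> 0`).
#' @param from start of the output grid (years; may be negative).
#' @return A `smoking_trajectory` data frame with columns `t, L, H, F, P,
#'   N, current_prev, past_prev, q, percap_cess, Qcum`. The heavy
#'   fraction `q` and per-capita cessation rate are `NA` where
#'   `L + H = 0`.
#' @examples
#' traj <- simulate_smoking(smoking_params(), horizon = 50)
#' tail(traj$q, 1)
#' @export
simulate_smoking <- function(params, horizon, grid_step = 0.1, from = 0) {
  validate_smoking_params(params)
  if (!is.numeric(horizon) || horizon <= 0) stop("horizon must be positive")
  if (!is.numeric(grid_step) || grid_step <= 0)
    stop("grid_step must be positive")
  times <- seq(from, from + horizon, by = grid_step)
  if (times[length(times)] < from + horizon)
    times <- c(times, from + horizon)
  y0 <- .init_state(params)
  solve_piece <- function(tt) {
    out <- deSolve::lsoda(y = y0, times = tt, func = smoking_rhs,
                          parms = params, rtol = 1e-8, atol = 1e-6)
    if (attr(out, "istate")[1L] < 0)
      stop("ODE integration failed to converge")
    out
  }
  neg <- times[times < 0]
  pos <- times[times >= 0]
  pieces <- list()
  if (length(neg))
    pieces$neg <- solve_piece(c(0, rev(neg)))[-1L, , drop = FALSE]
  # anchor the forward solve at t = 0 even when the grid skips it
  if (length(pos)) {
    drop_first <- !length(pos) || pos[1L] > 0
    pieces$pos <- solve_piece(unique(c(0, pos)))
    if (drop_first && nrow(pieces$pos) > length(pos))
      pieces$pos <- pieces$pos[-1L, , drop = FALSE]
  }
  if (!is.null(pieces$neg))
    pieces$neg <- pieces$neg[rev(seq_len(nrow(pieces$neg))), , drop = FALSE]
  out <- do.call(rbind, pieces)
  states <- out[, 2:6, drop = FALSE]
  tol <- 1e-6 * params$P0
  if (any(states[, 1:3] < -tol) ||
      any(states[, 4L] - rowSums(states[, 1:3, drop = FALSE]) < -tol))
    stop("state invariant violated beyond tolerance: ",
         "negative stock or never-smoker residual")
  states[, 1:3][states[, 1:3] < 0] <- 0
  trajectory_frame(out[, 1L], states, params)
}

#' @export
print.smoking_trajectory <- function(x, ...) {
  cat(sprintf("<smoking_trajectory> %d points, t in [%g, %g]\n",
              nrow(x), min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj a `smoking_trajectory` from [simulate_smoking()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "L", "H", "F", "P", "N",
                                           "current_prev", "past_prev",
                                           "q", "percap_cess")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Analytic equilibrium heavy-dependence fraction
#'
#' When the per-capita initiation rate is positive, the long-run
#' proportion of current smokers who are heavily dependent equals
#' `v / (v + lam * c + zeta * mu)`, with `v` and `c` evaluated at
#' `at_time`. The equilibrium does not depend on the initiation rate `u`
#' or the relapse rate `r`.
#'
#' @param params a [smoking_params()] object.
#' @param at_time time (years) at which the trending rates `v` and `c`
#'   are evaluated.
#' @return The equilibrium fraction, in `[0, 1]`.
#' @examples
#' equilibrium_q(smoking_params())  # 0.2 / 0.39 = 0.5128...
#' @export
equilibrium_q <- function(params, at_time = 0) {
  validate_smoking_params(params)
  v <- rate_at_time(params$v0, params$delta_v, at_time)
  cc <- rate_at_time(params$c0, params$delta_c, at_time)
  denom <- v + params$lam * cc + params$zeta * params$mu
  if (denom == 0)
    stop("equilibrium undefined: v, c and mu are all zero")
  v / denom
}
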