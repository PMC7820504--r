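#' Run the model to its behavioural equilibrium
#'
#' Integrates the model with constant rates until the heavy-dependence
#' fraction `q = H/(L+H)` has settled, and returns the terminal state.
#' Settling is defined as `|dq/dt| < tol_dqdt` per year and agreement
#' with the analytic equilibrium [equilibrium_q()] within `tol_q`.
#'
#' @param params a [smoking_params()] object with all trend rates zero
#'   (equilibration is defined for constant rates).
#' @param settle_years maximum years allowed to settle (the step-change
#'   experiments use 1000).
#' @param tol_dqdt tolerance on `|dq/dt|` (1/year).
#' @param tol_q tolerance on `|q - q_equilibrium|`.
#' @return A named list with the settled state (`t`, `L`, `H`, `F`, `P`)
#'   and its `q`.
#' @examples
#' eq <- equilibrate(smoking_params(), settle_years = 1000)
#' eq$q  # 0.5128...
#' @export
equilibrate <- function(params, settle_years = 1000,
                        tol_dqdt = 1e-8, tol_q = 1e-4) {
  validate_smoking_params(params)
  if (any(c(params$delta_u, params$delta_v, params$delta_c,
            params$delta_r, params$delta_g) != 0))
    stop("equilibrate() requires constant rates (all trend rates zero)")
  if (settle_years <= 0) stop("settle_years must be positive")
  traj <- simulate_smoking(params, horizon = settle_years,
                           grid_step = min(1, settle_years))
  end <- traj[nrow(traj), ]
  if (!is.finite(end$q))
    stop("failed to settle: smoking population went extinct")
  d <- smoking_derivatives(end[, c("L", "H", "F", "P")], params, t = end$t)
  # dq/dt = (H' L - H L') / (L+H)^2 with q = H/(L+H)
  dqdt <- (d[["H"]] * end$L - end$H * d[["L"]]) / (end$L + end$H)^2
  qeq <- equilibrium_q(params, at_time = end$t)
  if (abs(dqdt) >= tol_dqdt || abs(end$q - qeq) >= tol_q)
    stop(sprintf(paste0("failed to settle within %g years: |dq/dt| = %.3g, ",
                        "|q - q*| = %.3g"),
                 settle_years, abs(dqdt), abs(end$q - qeq)))
  list(t = end$t, L = end$L, H = end$H, F = end$F, P = end$P, q = end$q)
}

.step_rates <- c("u", "v", "c", "r")

#' Step-change perturbation experiment
#'
#' Equilibrates the model, restarts the clock at 0, then at `onset` years
#' multiplies one per-capita rate (`u`, `v`, `c` or `r`) by `multiplier`,
#' instantaneously and permanently, and records the heavy-dependence
#' fraction `q(t)` over `horizon` years. The integration is split at the
#' onset so the solver never steps across the discontinuity; the stocks
#' are continuous at the step.
#'
#' @param params a [smoking_params()] object with constant rates.
#' @param rate which rate to perturb: `"u"`, `"v"`, `"c"` or `"r"`.
#' @param multiplier positive factor applied to the rate at the step
#'   (e.g. `0.7` for a 30% reduction, `1.1` for a 10% increase).
#' @param onset time of the step within the experiment window (years).
#' @param horizon experiment length (years), `> onset`.
#' @param grid_step output grid spacing (years).
#' @param settle_years years allowed for the pre-experiment
#'   equilibration.
#' @return A data frame of class `step_experiment` with columns `t`, `q`,
#'   `L`, `H`, `F`, `P`, plus attributes `q_before` (pre-step
#'   equilibrium) and `q_after` (analytic equilibrium under the perturbed
#'   rate).
#' @examples
#' ex <- run_step_experiment(smoking_params(), "c", 1.3, horizon = 100)
#' attr(ex, "q_after")  # new, lower equilibrium
#' @export
run_step_experiment <- function(params, rate, multiplier, onset = 10,
                                horizon = 200, grid_step = 0.25,
                                settle_years = 1000) {
  validate_smoking_params(params)
  if (!is.character(rate) || length(rate) != 1L || !(rate %in% .step_rates))
    stop("unknown target rate: must be one of ",
         paste(dQuote(.step_rates), collapse = ", "))
  if (!is.numeric(multiplier) || multiplier <= 0)
    stop("multiplier must be positive")
  if (onset < 0 || onset >= horizon) stop("onset must lie in [0, horizon)")
  eq <- equilibrate(params, settle_years = settle_years)
  base <- params
  base$L0 <- eq$L; base$H0 <- eq$H; base$F0 <- eq$F; base$P0 <- eq$P
  pre <- if (onset > 0)
    simulate_smoking(base, horizon = onset, grid_step = grid_step)
  else
    simulate_smoking(base, horizon = grid_step,
                     grid_step = grid_step)[1L, , drop = FALSE]
  stepped <- base
  key <- paste0(rate, "0")
  stepped[[key]] <- stepped[[key]] * multiplier
  end <- pre[nrow(pre), ]
  stepped$L0 <- end$L; stepped$H0 <- end$H
  stepped$F0 <- end$F; stepped$P0 <- end$P
  post <- simulate_smoking(stepped, horizon = horizon - onset,
                           grid_step = grid_step)
  post$t <- post$t + onset
  keep <- c("t", "q", "L", "H", "F", "P")
  out <- rbind(as.data.frame(pre)[, keep],
               as.data.frame(post)[-1L, keep])
  structure(out, class = c("step_experiment", "data.frame"),
            rate = rate, multiplier = multiplier, onset = onset,
            q_before = equilibrium_q(params),
            q_after = equilibrium_q(stepped))
}

#' Run the full grid of step-change experiments
#'
#' Convenience driver for the standard experiment grid: `u`, `v` and `r`
#' reduced by 10%, 20% and 30% and increased by 10%; `c` increased by
#' 10%, 20% and 30% and reduced by 10%.
#'
#' @param params a [smoking_params()] object with constant rates.
#' @param onset,horizon,grid_step,settle_years passed to
#'   [run_step_experiment()].
#' @return A named list of `step_experiment` data frames, names like
#'   `"c_x1.3"`.
#' @export
step_experiment_grid <- function(params = smoking_params(), onset = 10,
                                 horizon = 200, grid_step = 0.25,
                                 settle_years = 1000) {
  grid <- rbind(
    expand.grid(rate = c("u", "v", "r"),
                multiplier = c(0.9, 0.8, 0.7, 1.1),
                stringsAsFactors = FALSE),
    expand.grid(rate = "c", multiplier = c(1.1, 1.2, 1.3, 0.9),
                stringsAsFactors = FALSE))
  out <- Map(function(rate, mult)
    run_step_experiment(params, rate, mult, onset = onset,
                        horizon = horizon, grid_step = grid_step,
                        settle_years = settle_years),
    grid$rate, grid$multiplier)
  names(out) <- sprintf("%s_x%g", grid$rate, grid$multiplier)
  out
}

#' @export
print.step_experiment <- function(x, ...) {
  cat(sprintf(
    "<step_experiment> rate %s x%g at t = %g; q: %.4f -> %.4f (equilibria)\n",
    attr(x, "rate"), attr(x, "multiplier"), attr(x, "onset"),
    attr(x, "q_before"), attr(x, "q_after")))
  invisible(x)
}
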