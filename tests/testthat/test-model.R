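test_that("trending rates follow base * exp(delta * t)", {
  expect_identical(rate_at_time(0.4, 0, 10), 0.4)
  expect_identical(rate_at_time(0.4, -0.05, 0), 0.4)
  expect_equal(rate_at_time(0.01, -0.1, 10), 0.01 * exp(-1))
  expect_equal(rate_at_time(0.01, -0.1, 10), 0.003678794, tolerance = 1e-6)
  # vectorised over t
  expect_equal(rate_at_time(2, 0.1, c(0, 1, 2)), 2 * exp(0.1 * c(0, 1, 2)))
})

test_that("stock derivatives equal the stated flow balances", {
  p <- baseline_params()
  st <- list(L = 4e4, H = 6e4, F = 1.5e5, P = 1e6)
  d <- smoking_derivatives(st, p, t = 0)
  # hand sums of the individual flows at the baseline state:
  # initiation u*N, relapse r*F, progression v*L, cessation c*L,
  # mortality mu*L -> dL; and analogously for H and F
  expect_equal(d[["L"]], 7500 + 30000 - 8000 - 16000 - 800)   # = 12700
  expect_equal(d[["H"]], 8000 - 9600 - 1800)                  # = -3400
  expect_equal(d[["F"]], 16000 + 9600 - 30000 - 1500)         # = -5900
  expect_equal(d[["P"]], 0)  # g = 0: constant total population

  # empty smoking stocks: only initiation from the never-smoker pool
  d0 <- smoking_derivatives(list(L = 0, H = 0, F = 0, P = 1e6), p, 0)
  expect_equal(d0[["L"]], p$u0 * 1e6)
  expect_equal(d0[["H"]], 0)
  expect_equal(d0[["F"]], 0)

  # time-varying rates are evaluated at t
  pd <- baseline_params(delta_c = -0.1)
  d10 <- smoking_derivatives(st, pd, t = 10)
  c10 <- 0.4 * exp(-1)
  expect_equal(d10[["F"]], c10 * 4e4 + 0.4 * c10 * 6e4 - 30000 - 1500)

  expect_error(smoking_derivatives(list(L = -1, H = 0, F = 0, P = 1e6), p),
               "negative stock")
  expect_error(smoking_derivatives(list(L = 9e5, H = 2e5, F = 0, P = 1e6), p),
               "residual")
})

test_that("long integration reaches the analytic equilibrium fraction", {
  traj <- simulate_smoking(baseline_params(), horizon = 1000, grid_step = 1)
  expect_equal(tail(traj$q, 1), 0.5128205, tolerance = 1e-3)
  expect_equal(tail(traj$q, 1), equilibrium_q(baseline_params()),
               tolerance = 1e-4)
})

test_that("degenerate flow settings behave as stated", {
  # no flows at all: every stock frozen
  p0 <- smoking_params(u0 = 0, v0 = 0, c0 = 0, r0 = 0, g0 = 0, mu = 0)
  traj <- simulate_smoking(p0, horizon = 50, grid_step = 5)
  for (col in c("L", "H", "F", "P"))
    expect_equal(traj[[col]], rep(traj[[col]][1], nrow(traj)),
                 tolerance = 1e-12)
  # zero growth: P constant despite deaths from the smoking stocks
  traj2 <- simulate_smoking(baseline_params(), horizon = 200, grid_step = 10)
  expect_equal(traj2$P, rep(1e6, nrow(traj2)), tolerance = 1e-10)
  # positive growth: P grows exponentially
  pg <- baseline_params(g0 = 0.01)
  traj3 <- simulate_smoking(pg, horizon = 100, grid_step = 100)
  expect_equal(tail(traj3$P, 1), 1e6 * exp(1), tolerance = 1e-6)
})

test_that("stocks and the never-smoker residual stay nonnegative", {
  set.seed(42)
  for (i in 1:10) {
    p <- random_constant_params()
    traj <- simulate_smoking(p, horizon = 200, grid_step = 2)
    tol <- 1e-6 * p$P0
    expect_true(all(traj$L >= -tol & traj$H >= -tol & traj$F >= -tol))
    expect_true(all(traj$N >= -tol))
  }
})

test_that("halving the output grid step leaves the trajectory unchanged", {
  p <- baseline_params(delta_c = -0.02, delta_v = -0.01, g0 = 0.01)
  t1 <- simulate_smoking(p, horizon = 50, grid_step = 0.5)
  t2 <- simulate_smoking(p, horizon = 50, grid_step = 0.25)
  common <- t2$t %in% t1$t
  for (col in c("L", "H", "F", "P", "q", "current_prev", "percap_cess")) {
    a <- t1[[col]]
    b <- t2[[col]][common]
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-6)
  }
})

test_that("equilibrium fraction formula matches its closed form and edge cases", {
  expect_equal(equilibrium_q(baseline_params()), 0.2 / 0.39)
  expect_equal(round(100 * equilibrium_q(baseline_params()), 1), 51.3)
  # no progression: no heavily dependent smokers at equilibrium
  expect_equal(equilibrium_q(smoking_params(v0 = 0)), 0)
  # 30% cessation increase: 0.2 / (0.2 + 0.4*0.52 + 0.03)
  expect_equal(equilibrium_q(baseline_params(c0 = 0.52)), 0.2 / 0.438)
  # trending rates are evaluated at the requested time
  pt <- baseline_params(delta_v = -0.1)
  v10 <- 0.2 * exp(-1)
  expect_equal(equilibrium_q(pt, at_time = 10), v10 / (v10 + 0.16 + 0.03))
  expect_error(equilibrium_q(smoking_params(v0 = 0, c0 = 0, mu = 0)),
               "undefined")
})

test_that("simulated equilibrium matches the formula for random parameter sets", {
  set.seed(7)
  for (i in 1:20) {
    p <- random_constant_params()
    traj <- simulate_smoking(p, horizon = 1000, grid_step = 10)
    expect_lt(abs(tail(traj$q, 1) - equilibrium_q(p)), 1e-4)
  }
})

test_that("the equilibrium is independent of initiation and relapse rates", {
  # analytically: the formula contains neither u nor r
  p1 <- baseline_params(u0 = 0.01, r0 = 0.2)
  p2 <- baseline_params(u0 = 0.04, r0 = 0.05)
  expect_identical(equilibrium_q(p1), equilibrium_q(p2))
  # and dynamically: long simulations at different u0, r0 converge to it
  for (p in list(p1, p2)) {
    traj <- simulate_smoking(p, horizon = 1000, grid_step = 20)
    expect_lt(abs(tail(traj$q, 1) - equilibrium_q(p1)), 1e-4)
  }
})

test_that("equilibrium fraction is monotone in each rate parameter", {
  p <- baseline_params()
  h <- 1e-6
  dq <- function(field, delta = h) {
    p2 <- p
    p2[[field]] <- p2[[field]] + delta
    equilibrium_q(p2) - equilibrium_q(p)
  }
  expect_lt(dq("c0"), 0)    # more cessation -> softer population
  expect_lt(dq("lam"), 0)
  expect_lt(dq("zeta"), 0)
  expect_lt(dq("mu"), 0)
  expect_gt(dq("v0"), 0)    # more progression -> harder population
})

test_that("trajectory reports q as missing when the smoking population is empty", {
  p <- smoking_params(L0 = 0, H0 = 0, F0 = 1e5, u0 = 0, r0 = 0)
  traj <- simulate_smoking(p, horizon = 10, grid_step = 1)
  expect_true(all(is.na(traj$q)))
  expect_true(all(is.na(traj$percap_cess)))
})

test_that("trajectories can extend before the initial condition", {
  p <- baseline_params(delta_c = -0.05)
  traj <- simulate_smoking(p, horizon = 6, grid_step = 0.5, from = -1)
  expect_equal(min(traj$t), -1)
  # the state at t = 0 is the initial condition in both directions
  row0 <- traj[abs(traj$t) < 1e-9, ]
  expect_equal(row0$L, p$L0, tolerance = 1e-8)
  expect_equal(row0$Qcum, 0, tolerance = 1e-6)
  # cumulative quit flow is negative before t = 0 and increasing throughout
  expect_lt(traj$Qcum[1], 0)
  expect_true(all(diff(traj$Qcum) > 0))
})

test_that("compiled fast path agrees with the adaptive reference solver", {
  p <- baseline_params(delta_c = -0.03, delta_v = -0.02, delta_u = 0.01,
                       g0 = 0.012, delta_g = 0.01)
  times <- c(-1, -0.5, 0, 0.5, 3.5, 7.25, 15.5)
  fast <- smokedyn:::integrate_states(p, times)
  ref <- simulate_smoking(p, horizon = 16.5, grid_step = 0.25, from = -1)
  for (k in seq_along(times)) {
    row <- ref[abs(ref$t - times[k]) < 1e-9, ]
    expect_equal(unname(fast[k, 1L]), row$L, tolerance = 1e-7)
    expect_equal(unname(fast[k, 2L]), row$H, tolerance = 1e-7)
    expect_equal(unname(fast[k, 3L]), row$F, tolerance = 1e-7)
    expect_equal(unname(fast[k, 4L]), row$P, tolerance = 1e-9)
    expect_equal(unname(fast[k, 5L]), row$Qcum, tolerance = 1e-6)
  }
})

test_that("trajectory CSV export carries the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  traj <- simulate_smoking(baseline_params(), horizon = 5, grid_step = 1)
  write_trajectory_csv(traj, path)
  back <- read.csv(path)
  expect_named(back, c("t", "L", "H", "F", "P", "N", "current_prev",
                       "past_prev", "q", "percap_cess"))
  expect_equal(back$q, traj$q, tolerance = 1e-12)
})
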