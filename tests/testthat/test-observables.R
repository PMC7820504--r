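# Mapping from model trajectories to the four survey-observable series,
# and the overdispersed-Poisson likelihood.

test_that("stock observables read straight off a frozen trajectory", {
  # freeze the dynamics so mid-year readout equals the initial stocks
  p <- smoking_params(u0 = 0, v0 = 0, c0 = 0, r0 = 0, g0 = 0, mu = 0)
  traj <- simulate_smoking(p, horizon = 8, grid_step = 0.1, from = -1)
  m <- predict_observables(traj, p, years = c(2001, 2004), year_zero = 2001)
  get <- function(kind, year) m$m[m$kind == kind & m$year == year]
  expect_equal(get("current_smokers", 2001), 1e5, tolerance = 1e-9)
  expect_equal(get("former_smokers", 2001), 1.5e5, tolerance = 1e-9)
  expect_equal(get("pack_a_day", 2004), 6e4, tolerance = 1e-9)
  expect_equal(get("past_year_quitters", 2004), 0, tolerance = 1e-9)
})

test_that("quitters equal c*L + lam*c*H exactly for constant stocks", {
  # hand-built trajectory with frozen stocks and constant cessation rate:
  # the trailing-year integral of the quit flow is then exact
  p <- baseline_params()
  tgrid <- seq(-1, 16, by = 0.25)
  flow <- p$c0 * 4e4 + p$lam * p$c0 * 6e4
  traj <- structure(
    data.frame(t = tgrid, L = 4e4, H = 6e4, F = 1.5e5, P = 1e6,
               Qcum = flow * tgrid),
    class = c("smoking_trajectory", "data.frame"))
  m <- predict_observables(traj, p, years = 2001:2003,
                           kinds = "past_year_quitters", year_zero = 2001)
  expect_equal(m$m, rep(flow, 3), tolerance = 1e-12)
})

test_that("quitters match independent fine-step quadrature of the quit flow", {
  p <- baseline_params(delta_c = -0.03, delta_v = -0.02)
  traj <- simulate_smoking(p, horizon = 8, grid_step = 0.05, from = -1)
  m <- predict_observables(traj, p, years = c(2001, 2005),
                           kinds = "past_year_quitters", year_zero = 2001)
  # oracle: midpoint rule over (t-1, t] with the flow rebuilt from the
  # interpolated stocks and the analytic c(s)
  fL <- splinefun(traj$t, traj$L)
  fH <- splinefun(traj$t, traj$H)
  quad <- function(t_end) {
    s <- seq(t_end - 1, t_end, length.out = 2001)
    mid <- (s[-1] + s[-length(s)]) / 2
    cs <- rate_at_time(p$c0, p$delta_c, mid)
    sum(cs * (fL(mid) + p$lam * fH(mid))) * (s[2] - s[1])
  }
  expect_equal(m$m[1], quad(0.5), tolerance = 1e-3)
  expect_equal(m$m[2], quad(4.5), tolerance = 1e-3)
})

test_that("expected counts scale linearly with population size", {
  p1 <- baseline_params(g0 = 0.01, delta_c = -0.02)
  p2 <- baseline_params(P0 = 2e6, L0 = 8e4, H0 = 1.2e5, F0 = 3e5,
                        g0 = 0.01, delta_c = -0.02)
  t1 <- simulate_smoking(p1, horizon = 8, grid_step = 0.05, from = -1)
  t2 <- simulate_smoking(p2, horizon = 8, grid_step = 0.05, from = -1)
  m1 <- predict_observables(t1, p1, years = c(2002, 2006), year_zero = 2001)
  m2 <- predict_observables(t2, p2, years = c(2002, 2006), year_zero = 2001)
  expect_equal(m2$m, 2 * m1$m, tolerance = 1e-8)
})

test_that("coverage violations and bad requests are signalled", {
  p <- baseline_params()
  traj <- simulate_smoking(p, horizon = 5, grid_step = 0.1)  # starts at 0
  # quitters for 2001 need the trajectory back to t = -0.5
  expect_error(predict_observables(traj, p, years = 2001, year_zero = 2001),
               "covers")
  expect_error(predict_observables(traj, p, years = 2030, year_zero = 2001),
               "covers")
  expect_error(predict_observables(traj, p,
                                   years = data.frame(year = 2002,
                                                      kind = "nope")),
               "unknown observable kind")
})

test_that("log-likelihood equals the factorial-form Poisson mass", {
  obs1 <- data.frame(year = 2001, kind = "current_smokers", count = 3)
  expect_equal(log_likelihood(obs1, m = 3), 3 * log(3) - 3 - log(6),
               tolerance = 1e-12)
  expect_equal(log_likelihood(obs1, m = 3), -1.4959, tolerance = 1e-4)
  # zero count: mass is exp(-m)
  obs0 <- data.frame(year = 2001, kind = "current_smokers", count = 0)
  expect_equal(log_likelihood(obs0, m = 2), -2, tolerance = 1e-12)
  # factorial form with a nonzero deviate, checked to 1e-10
  y <- 17; mm <- 12.3; eps <- 0.25
  obs <- data.frame(year = 2001, kind = "pack_a_day", count = y)
  direct <- y * log(mm * exp(eps)) - mm * exp(eps) - lfactorial(y)
  expect_equal(log_likelihood(obs, m = mm, epsilon = eps), direct,
               tolerance = 1e-10)
})

test_that("zero overdispersion reduces the likelihood to plain Poisson", {
  obs <- data.frame(year = c(2001, 2004, 2007),
                    kind = "current_smokers", count = c(5L, 9L, 2L))
  mm <- c(4.2, 8.8, 3.1)
  expect_identical(log_likelihood(obs, mm, epsilon = 0),
                   sum(dpois(obs$count, mm, log = TRUE)))
})

test_that("conditional masses sum to one over the count support", {
  mm <- 2.5; eps <- 0.4
  total <- sum(vapply(0:300, function(y) {
    obs <- data.frame(year = 2001, kind = "current_smokers", count = y)
    exp(log_likelihood(obs, m = mm, epsilon = eps))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("likelihood is invariant to observation order", {
  obs <- data.frame(year = c(2001, 2004, 2001, 2004),
                    kind = rep(c("current_smokers", "pack_a_day"), each = 2),
                    count = c(11L, 7L, 5L, 3L))
  mdf <- data.frame(year = obs$year, kind = obs$kind,
                    m = c(10, 8, 6, 2.5))
  eps <- c(0.1, -0.2, 0, 0.05)
  base <- log_likelihood(obs, mdf, epsilon = eps)
  perm <- c(3, 1, 4, 2)
  obs_p <- obs[perm, ]
  # re-sort within series so the survey-year monotonicity contract holds
  obs_p <- obs_p[order(obs_p$kind, obs_p$year), ]
  key <- paste(obs_p$year, obs_p$kind)
  eps_p <- eps[match(key, paste(obs$year, obs$kind))]
  expect_equal(log_likelihood(obs_p, mdf, epsilon = eps_p), base,
               tolerance = 1e-12)
})

test_that("likelihood rejects invalid inputs", {
  obs <- data.frame(year = 2001, kind = "current_smokers", count = 3)
  expect_error(log_likelihood(obs, m = 0), "positive")
  expect_error(log_likelihood(obs, m = -2), "positive")
  expect_error(
    log_likelihood(data.frame(year = 2001, kind = "current_smokers",
                              count = -1), m = 2),
    "nonnegative integers")
  expect_error(
    log_likelihood(data.frame(year = 2001, kind = "current_smokers",
                              count = 2.5), m = 2),
    "nonnegative integers")
  expect_error(
    log_likelihood(data.frame(year = 2001, kind = "cigars", count = 1),
                   m = 2),
    "unknown observable kind")
})

test_that("survey CSV round-trips and enforces the series contract", {
  d <- tiny_survey()
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(d, path)
  back <- read_survey_csv(path)
  expect_equal(back, d)
  bad <- d
  bad$year[2] <- 2001  # duplicate year within a series
  expect_error(validate_survey_data(bad), "strictly increasing")
})
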