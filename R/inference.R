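#' Default priors for Bayesian calibration
#'
#' The free parameters of a calibration are the four fractional trend
#' rates `delta_u, delta_v, delta_c, delta_r`, the initial per-capita
#' rates `u0, v0, c0, r0`, the initial numbers of current (`C0`) and
#' former (`F0`) smokers, the initial heavy-dependence fraction `q0`
#' (current smokers are split as `L0 = (1-q0) C0`, `H0 = q0 C0`), one
#' overdispersion scale `sigma` per observed series, and the latent
#' per-observation deviates `epsilon`. Defaults: normal(0, 0.05) on each
#' trend rate (per-year fractional changes of a few percent); lognormal
#' priors on the initial rates centred at the baseline simulation values
#' with unit log-SD; lognormal priors on `C0` and `F0` centred at 20%
#' and 25% of the fixed population `P0` with unit log-SD;
#' uniform(0, 1) on `q0`; half-normal(0, 0.5) on each `sigma`.
#'
#' @param fixed the fixed-parameter list (see [fit_smoking_model()]);
#'   used to centre the stock priors on `P0`.
#' @return A nested list of prior settings, each element overridable.
#' @export
default_priors <- function(fixed = list(P0 = 1e6)) {
  list(
    delta = list(mean = 0, sd = 0.05),
    u0 = list(meanlog = log(0.01), sdlog = 1),
    v0 = list(meanlog = log(0.2), sdlog = 1),
    c0 = list(meanlog = log(0.4), sdlog = 1),
    r0 = list(meanlog = log(0.2), sdlog = 1),
    C0 = list(meanlog = log(0.20 * fixed$P0), sdlog = 1),
    F0 = list(meanlog = log(0.25 * fixed$P0), sdlog = 1),
    q0 = list(dist = "uniform"),
    sigma = list(scale = 0.5))
}

#' Default fixed (non-sampled) parameters for calibration
#'
#' The mortality and ratio parameters `mu`, `zeta`, `eta`, `lam` and the
#' population block `P0`, `g0`, `delta_g` are held fixed during
#' calibration; everything else is estimated.
#'
#' @param P0,g0,delta_g population size and growth settings.
#' @param mu,zeta,eta,lam mortality and ratio constants.
#' @return A named list suitable for the `fixed` argument of
#'   [fit_smoking_model()].
#' @export
default_fixed <- function(P0 = 1e6, g0 = 0, delta_g = 0,
                          mu = 0.02, zeta = 1.5, eta = 0.5, lam = 0.4) {
  list(P0 = P0, g0 = g0, delta_g = delta_g,
       mu = mu, zeta = zeta, eta = eta, lam = lam)
}

.theta_names <- c("delta_u", "delta_v", "delta_c", "delta_r",
                  "u0", "v0", "c0", "r0", "C0", "F0", "q0")

# natural-scale theta (named vector) -> smoking_params
.theta_to_params <- function(th, fixed) {
  smoking_params(
    P0 = fixed$P0,
    L0 = (1 - th[["q0"]]) * th[["C0"]], H0 = th[["q0"]] * th[["C0"]],
    F0 = th[["F0"]],
    mu = fixed$mu, zeta = fixed$zeta, eta = fixed$eta, lam = fixed$lam,
    u0 = th[["u0"]], v0 = th[["v0"]], c0 = th[["c0"]], r0 = th[["r0"]],
    g0 = fixed$g0,
    delta_u = th[["delta_u"]], delta_v = th[["delta_v"]],
    delta_c = th[["delta_c"]], delta_r = th[["delta_r"]],
    delta_g = fixed$delta_g)
}

# unconstrained z -> natural theta; order matches .theta_names
.z_to_theta <- function(z) {
  stats::setNames(c(z[1:4], exp(z[5:10]), stats::plogis(z[11])),
                  .theta_names)
}

# log prior density of z (includes transform Jacobians)
.log_prior_z <- function(z, priors, fixed) {
  th <- .z_to_theta(z)
  if (th[9] + th[10] > fixed$P0) return(-Inf)  # C0 + F0 <= P0
  lp <- sum(stats::dnorm(z[1:4], priors$delta$mean, priors$delta$sd,
                         log = TRUE))
  rl <- c("u0", "v0", "c0", "r0", "C0", "F0")
  for (i in seq_along(rl)) {
    pr <- priors[[rl[i]]]
    lp <- lp + stats::dnorm(z[4L + i], pr$meanlog, pr$sdlog, log = TRUE)
  }
  # uniform(0,1) on q0, logit transform Jacobian q0 (1 - q0)
  q0 <- th[11]
  lp + log(q0) + log1p(-q0)
}

# build the expected-count function for a fixed data layout: returns
# function(theta_natural) -> m vector aligned with the rows of `data`,
# or NULL when the trajectory is degenerate
.make_m_fun <- function(data, fixed, year_zero, hmax = 0.025) {
  tt <- survey_time(data$year, year_zero)
  need <- sort(unique(c(tt, tt[data$kind == "past_year_quitters"] - 1)))
  it <- match(tt, need)
  itm1 <- match(tt - 1, need)  # NA except where needed
  kind <- data$kind
  function(th) {
    p <- tryCatch(.theta_to_params(th, fixed), error = function(e) NULL)
    if (is.null(p)) return(NULL)
    s <- .integrate_states_cpp(.pvec(p), .init_state(p), need, hmax)
    m <- numeric(length(tt))
    for (i in seq_along(tt)) {
      m[i] <- switch(kind[i],
        current_smokers = s[it[i], 1L] + s[it[i], 2L],
        former_smokers = s[it[i], 3L],
        pack_a_day = s[it[i], 2L],
        past_year_quitters = s[it[i], 5L] - s[itm1[i], 5L])
    }
    if (any(!is.finite(m)) || any(m <= 0)) NULL else m
  }
}

# split-chain potential scale reduction factor (rank-free classic form)
split_rhat <- function(x) {
  # x: iterations x chains matrix
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(sub)
  vars <- apply(sub, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Calibrate the smoking model to survey count series
#'
#' Bayesian fit of the model to survey counts by adaptive Markov chain
#' Monte Carlo. The posterior is over the trend rates, initial
#' per-capita rates, initial current/former smoker numbers, initial
#' heavy-dependence fraction, per-series overdispersion scales `sigma`,
#' and the latent per-observation deviates `epsilon` (sampled jointly
#' with the structural parameters, matching the conditional
#' overdispersed-Poisson likelihood of [log_likelihood()]). Structural
#' parameters move as a block with a multivariate-normal random-walk
#' proposal whose covariance is adapted during warmup; `epsilon` and
#' `sigma` have vectorised univariate random-walk updates.
#'
#' Convergence is assessed with the split-chain potential scale
#' reduction factor; a fit with any value at or above 1.01 is returned
#' flagged (`converged = FALSE`), never silently.
#'
#' @param data survey observations (columns `year`, `kind`, `count`);
#'   must contain at least two survey years for both the
#'   current-smokers and former-smokers series.
#' @param priors prior settings, as [default_priors()].
#' @param fixed fixed parameters, as [default_fixed()].
#' @param chains number of chains.
#' @param iter post-warmup draws per chain.
#' @param warmup adaptation iterations per chain (discarded).
#' @param seed integer seed; identical seed and configuration give
#'   identical draws.
#' @param year_zero calendar year at which model time is 0 (the fitted
#'   initial rates apply at the start of this year).
#' @param use_likelihood set `FALSE` to sample from the prior only
#'   (sampler-validation runs).
#' @param init optional named list overriding initial values for the
#'   structural parameters (natural scale).
#' @return An object of class `smoking_fit`: draws (natural scale, one
#'   row per draw with `.chain`/`.iter` indices), per-parameter
#'   split-Rhat, acceptance rates, the `converged` flag, and the
#'   configuration needed for posterior prediction.
#' @export
fit_smoking_model <- function(data, priors = NULL, fixed = default_fixed(),
                              chains = 4, iter = 2000, warmup = 3000,
                              seed = 1, year_zero = 2001,
                              use_likelihood = TRUE, init = NULL) {
  validate_survey_data(data)
  if (use_likelihood) {
    for (k in c("current_smokers", "former_smokers"))
      if (sum(data$kind == k) < 2)
        stop("need at least two survey years of the ", k, " series")
  }
  if (is.null(priors)) priors <- default_priors(fixed)
  if (chains < 1 || iter < 2 || warmup < 100)
    stop("need chains >= 1, iter >= 2, warmup >= 100")
  set.seed(as.integer(seed))

  n_obs <- nrow(data)
  kinds <- sort(unique(data$kind))
  kind_idx <- match(data$kind, kinds)
  y <- data$count
  m_fun <- .make_m_fun(data, fixed, year_zero)
  d <- length(.theta_names)
  sig_scale <- priors$sigma$scale

  # data-informed starting centre for the structural block
  z_centre <- local({
    first_of <- function(k, default) {
      i <- which(data$kind == k)
      if (length(i)) data$count[i[which.min(data$year[i])]] else default
    }
    C0 <- first_of("current_smokers", 0.20 * fixed$P0)
    F0 <- first_of("former_smokers", 0.25 * fixed$P0)
    if (C0 + F0 > 0.95 * fixed$P0) {
      C0 <- 0.20 * fixed$P0
      F0 <- 0.25 * fixed$P0
    }
    pack <- first_of("pack_a_day", NA)
    q0 <- if (is.finite(pack) && pack < C0 && pack > 0) pack / C0 else 0.5
    z <- c(0, 0, 0, 0,
           priors$u0$meanlog, priors$v0$meanlog, priors$c0$meanlog,
           priors$r0$meanlog, log(C0), log(F0), stats::qlogis(q0))
    if (!is.null(init)) {
      th <- init
      for (nm in names(th)) {
        j <- match(nm, .theta_names)
        if (is.na(j)) stop("unknown init parameter: ", nm)
        z[j] <- if (j <= 4) th[[nm]] else if (j <= 10) log(th[[nm]])
                else stats::qlogis(th[[nm]])
      }
    }
    z
  })

  eps_names <- sprintf("eps_%s_%d", data$kind, data$year)
  sig_names <- paste0("sigma_", kinds)
  par_names <- c(.theta_names, sig_names, eps_names)
  n_total <- iter * chains
  draws <- matrix(NA_real_, n_total, length(par_names),
                  dimnames = list(NULL, par_names))
  chain_id <- integer(n_total)
  accept_theta <- numeric(chains)

  ll_vec_of <- function(m, eps) {
    if (!use_likelihood) return(numeric(n_obs))
    stats::dpois(y, m * exp(eps), log = TRUE)
  }

  for (ch in seq_len(chains)) {
    # jittered start
    z <- z_centre + c(stats::rnorm(4, 0, 0.01), stats::rnorm(6, 0, 0.1),
                      stats::rnorm(1, 0, 0.2))
    lp <- .log_prior_z(z, priors, fixed)
    m <- m_fun(.z_to_theta(z))
    tries <- 0
    while ((is.null(m) || !is.finite(lp)) && tries < 100) {
      z <- z_centre + c(stats::rnorm(4, 0, 0.01), stats::rnorm(6, 0, 0.1),
                        stats::rnorm(1, 0, 0.2))
      lp <- .log_prior_z(z, priors, fixed)
      m <- m_fun(.z_to_theta(z))
      tries <- tries + 1
    }
    if (is.null(m) || !is.finite(lp))
      stop("could not find a valid starting point")
    eps <- stats::rnorm(n_obs, 0, 0.01)
    logsig <- rep(log(0.1), length(kinds))
    ll <- ll_vec_of(m, eps)

    # proposal state
    S_chol <- diag(0.02, d)          # initial block proposal
    log_scale <- 0
    s_eps <- rep(0.2, n_obs)
    s_sig <- rep(0.4, length(kinds))
    hist_z <- matrix(NA_real_, warmup, d)
    n_acc <- 0; n_prop <- 0

    total_iter <- warmup + iter
    for (it in seq_len(total_iter)) {
      # --- structural block ---
      # Residual-preserving move: propose z' and shift each latent
      # deviate by log(m/m') so the Poisson means m * exp(eps) are
      # unchanged (identity Jacobian). The Poisson terms cancel from the
      # acceptance ratio, which involves only the structural prior and
      # the Gaussian prior on the deviates; this removes the severe
      # theta-epsilon coupling that large survey counts induce.
      sig_obs <- exp(logsig)[kind_idx]
      # mixture proposal: adapted random walk, or a differential-evolution
      # jump along the difference of two past warmup states (symmetric;
      # the history is frozen at the end of warmup so the post-warmup
      # kernel is fixed)
      n_hist <- min(it - 1L, warmup)
      use_de <- n_hist > 300 && stats::runif(1) < 0.5
      step <- if (use_de) {
        ab <- sample.int(n_hist, 2L)
        de_gamma <- if (stats::runif(1) < 0.1) 1 else 2.38 / sqrt(2 * d)
        de_gamma * (hist_z[ab[1L], ] - hist_z[ab[2L], ]) +
          stats::rnorm(d, 0, 1e-5)
      } else {
        exp(log_scale) * drop(S_chol %*% stats::rnorm(d))
      }
      z_prop <- z + step
      lp_prop <- .log_prior_z(z_prop, priors, fixed)
      acc <- FALSE
      if (is.finite(lp_prop)) {
        m_prop <- m_fun(.z_to_theta(z_prop))
        if (!is.null(m_prop)) {
          eps_shift <- if (use_likelihood) eps + log(m) - log(m_prop)
                       else eps
          lr <- (lp_prop +
                   sum(stats::dnorm(eps_shift, 0, sig_obs, log = TRUE))) -
                (lp + sum(stats::dnorm(eps, 0, sig_obs, log = TRUE)))
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            z <- z_prop; lp <- lp_prop; m <- m_prop; eps <- eps_shift
            acc <- TRUE
          }
        }
      }
      n_prop <- n_prop + 1
      if (acc) n_acc <- n_acc + 1

      # --- latent deviates (vectorised independent updates) ---
      ll <- ll_vec_of(m, eps)
      eps_prop <- eps + s_eps * stats::rnorm(n_obs)
      ll_prop <- ll_vec_of(m, eps_prop)
      dpr <- stats::dnorm(eps_prop, 0, sig_obs, log = TRUE) -
             stats::dnorm(eps, 0, sig_obs, log = TRUE)
      take <- log(stats::runif(n_obs)) < (ll_prop - ll + dpr)
      take[!is.finite(ll_prop)] <- FALSE
      eps[take] <- eps_prop[take]
      ll[take] <- ll_prop[take]

      # --- overdispersion scales (vectorised over series) ---
      ls_prop <- logsig + s_sig * stats::rnorm(length(kinds))
      sse <- as.numeric(rowsum(eps^2, kind_idx))
      nk <- tabulate(kind_idx, length(kinds))
      lpost_sig <- function(ls) {
        s2 <- exp(2 * ls)
        # sum of N(eps; 0, sigma) + half-normal(sigma; scale) + log-Jacobian
        -nk * ls - sse / (2 * s2) - exp(2 * ls) / (2 * sig_scale^2) + ls
      }
      take_s <- log(stats::runif(length(kinds))) <
        (lpost_sig(ls_prop) - lpost_sig(logsig))
      logsig[take_s] <- ls_prop[take_s]

      # --- warmup adaptation ---
      if (it <= warmup) {
        hist_z[it, ] <- z
        gamma <- min(0.25, 2 / sqrt(it))
        if (!use_de)
          log_scale <- log_scale + gamma * ((acc * 1) - 0.234)
        s_eps <- s_eps * exp(gamma * (take - 0.44))
        s_sig <- s_sig * exp(gamma * (take_s - 0.44))
        if (it >= 200 && it %% 200 == 0) {
          use <- hist_z[max(1, floor(it / 4)):it, , drop = FALSE]
          V <- stats::cov(use) + diag(1e-10, d)
          R <- tryCatch(chol(2.38^2 / d * V), error = function(e) NULL)
          if (!is.null(R)) S_chol <- t(R)
        }
        if (it == warmup) { n_acc <- 0; n_prop <- 0 }
      } else {
        row <- (ch - 1) * iter + (it - warmup)
        draws[row, ] <- c(.z_to_theta(z), exp(logsig), eps)
        chain_id[row] <- ch
      }
    }
    accept_theta[ch] <- n_acc / max(1, n_prop)
  }

  rhat <- vapply(seq_along(par_names), function(j) {
    split_rhat(matrix(draws[, j], nrow = iter, ncol = chains))
  }, numeric(1))
  names(rhat) <- par_names
  structural <- c(.theta_names, sig_names)
  converged <- all(rhat[structural] < 1.01, na.rm = TRUE)
  if (!converged)
    warning("chains not converged: max split-Rhat = ",
            sprintf("%.3f", max(rhat[structural], na.rm = TRUE)),
            " (fit returned flagged)", call. = FALSE)

  structure(list(
    draws = cbind(data.frame(.chain = chain_id,
                             .iter = rep(seq_len(iter), chains)),
                  as.data.frame(draws)),
    rhat = rhat,
    converged = converged,
    accept_theta = accept_theta,
    data = data, fixed = fixed, priors = priors,
    year_zero = year_zero, chains = chains, iter = iter,
    warmup = warmup, seed = seed,
    use_likelihood = use_likelihood),
    class = "smoking_fit")
}

#' @export
print.smoking_fit <- function(x, ...) {
  cat(sprintf("<smoking_fit> %d chains x %d draws (%d warmup)%s\n",
              x$chains, x$iter, x$warmup,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  max split-Rhat (structural): %.3f; mean block acceptance: %.2f\n",
              max(x$rhat[c(.theta_names, grep("^sigma_", names(x$rhat),
                                              value = TRUE))], na.rm = TRUE),
              mean(x$accept_theta)))
  print(utils::head(summarize_posterior(x), 15))
  invisible(x)
}

#' Posterior summaries
#'
#' Per-parameter posterior median and central 95% interval, the
#' split-chain Rhat, and — for the fractional trend-rate parameters —
#' the posterior probability that the rate is negative (the softening /
#' declining-rates diagnostic).
#'
#' @param fit a `smoking_fit` object (or its draws data frame).
#' @param params parameters to summarise (default: all structural
#'   parameters and overdispersion scales).
#' @return A data frame with columns `parameter`, `median`, `q2.5`,
#'   `q97.5`, `p_negative`, `rhat`.
#' @export
summarize_posterior <- function(fit, params = NULL) {
  draws <- if (inherits(fit, "smoking_fit")) fit$draws else fit
  if (nrow(draws) == 0) stop("empty draw set")
  all_p <- setdiff(names(draws), c(".chain", ".iter"))
  if (is.null(params))
    params <- setdiff(all_p, grep("^eps_", all_p, value = TRUE))
  qs <- vapply(params, function(p)
    stats::quantile(draws[[p]], c(0.5, 0.025, 0.975), names = FALSE),
    numeric(3))
  pneg <- vapply(params, function(p)
    if (grepl("^delta_", p)) mean(draws[[p]] < 0) else NA_real_,
    numeric(1))
  rh <- if (inherits(fit, "smoking_fit"))
    unname(fit$rhat[params]) else rep(NA_real_, length(params))
  data.frame(parameter = params,
             median = qs[1L, ], q2.5 = qs[2L, ], q97.5 = qs[3L, ],
             p_negative = pneg, rhat = rh, row.names = NULL)
}

#' Posterior-predictive trajectory bands
#'
#' Draws `n_sims` parameter vectors from the posterior (uniformly, with
#' replacement if `n_sims` exceeds the number available — noted in the
#' result's attributes), runs the deterministic model for each, and
#' returns pointwise quantile bands of the requested derived outputs at
#' mid-year of each requested calendar year.
#'
#' @param fit a converged (or flagged) `smoking_fit`.
#' @param n_sims number of posterior simulations (the headline analyses
#'   use 1000).
#' @param outputs any of `"current_prev"`, `"past_prev"`, `"q"`,
#'   `"percap_cess"`.
#' @param years calendar years at which bands are evaluated.
#' @param probs quantile levels of the bands.
#' @return A data frame with columns `output`, `year` and one column per
#'   quantile (e.g. `q2.5`, `q50`, `q97.5`).
#' @export
posterior_predictive <- function(fit, n_sims = 1000,
                                 outputs = c("current_prev", "past_prev",
                                             "q", "percap_cess"),
                                 years = NULL,
                                 probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(fit, "smoking_fit"))
  outputs <- match.arg(outputs, several.ok = TRUE)
  draws <- fit$draws
  if (nrow(draws) == 0) stop("empty draw set")
  if (is.null(years))
    years <- seq(min(fit$data$year), max(fit$data$year))
  replaced <- n_sims > nrow(draws)
  idx <- sample.int(nrow(draws), n_sims, replace = replaced)
  tt <- survey_time(years, fit$year_zero)
  sims <- array(NA_real_, c(n_sims, length(years), length(outputs)),
                dimnames = list(NULL, years, outputs))
  for (s in seq_len(n_sims)) {
    th <- unlist(draws[idx[s], .theta_names])
    p <- .theta_to_params(th, fit$fixed)
    st <- .integrate_states_cpp(.pvec(p), .init_state(p), tt, 0.025)
    L <- st[, 1L]; H <- st[, 2L]; F <- st[, 3L]; P <- st[, 4L]
    cc <- rate_at_time(p$c0, p$delta_c, tt)
    cur <- L + H
    vals <- list(current_prev = cur / P, past_prev = F / P,
                 q = ifelse(cur > 0, H / cur, NA_real_),
                 percap_cess = ifelse(cur > 0,
                                      (cc * L + p$lam * cc * H) / cur,
                                      NA_real_))
    for (o in outputs) sims[s, , o] <- vals[[o]]
  }
  out <- do.call(rbind, lapply(outputs, function(o) {
    qm <- t(apply(sims[, , o, drop = FALSE], 2L, stats::quantile,
                  probs = probs, na.rm = TRUE))
    df <- data.frame(output = o, year = years)
    colnames(qm) <- paste0("q", probs * 100)
    cbind(df, qm)
  }))
  rownames(out) <- NULL
  structure(out, n_sims = n_sims, sampled_with_replacement = replaced)
}

#' Write / read posterior draws as CSV
#'
#' One row per draw, one column per named parameter plus the
#' `.chain`/`.iter` indices.
#'
#' @param fit a `smoking_fit` object.
#' @param path file path.
#' @return `write_posterior_csv()` returns `path` invisibly;
#'   `read_posterior_csv()` returns the draws data frame.
#' @export
write_posterior_csv <- function(fit, path) {
  utils::write.csv(fit$draws, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posterior_csv
#' @export
read_posterior_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
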