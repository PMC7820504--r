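#' Australia-like true parameter set for synthetic studies
#'
#' A default "Australia-like" parameterization for synthetic-survey and
#' parameter-recovery experiments: a population of 20 million aged-14+
#' persons, initial current-smoking prevalence of 23.1% with 52.1% of
#' smokers heavily dependent, former-smoker prevalence of 25%, the
#' baseline per-capita behaviour rates, and negative fractional trend
#' rates (a mature tobacco-control environment in which initiation,
#' progression, cessation and relapse all decline). The trend rates are
#' calibrated so the generating trajectory reproduces the reported
#' Australian declines over 2001-2016: current smoking prevalence
#' falling to 14.6% and the heavy-dependence fraction to 36.9% by
#' mid-2016.
#'
#' @return A [smoking_params()] object.
#' @export
australia_like_params <- function() {
  P0 <- 2e7
  C0 <- 0.231 * P0
  q0 <- 0.521
  smoking_params(
    P0 = P0,
    L0 = (1 - q0) * C0, H0 = q0 * C0, F0 = 0.25 * P0,
    mu = 0.02, zeta = 1.5, eta = 0.5, lam = 0.4,
    u0 = 0.01, v0 = 0.2, c0 = 0.4, r0 = 0.2,
    g0 = 0.012,
    delta_u = -0.02, delta_v = -0.082, delta_c = -0.024, delta_r = -0.03,
    delta_g = 0)
}

#' Specification of a synthetic survey data set
#'
#' Bundles everything needed to generate (and exactly regenerate) a
#' survey-like data set: the true model parameters, the survey years,
#' the per-series overdispersion scales, an optional per-series
#' year-availability mask, and the seed.
#'
#' @param true_params the generating [smoking_params()].
#' @param survey_years calendar years of the surveys (default: the
#'   triennial 2001-2016 schedule).
#' @param sigma_by_series named numeric vector of overdispersion scales,
#'   one per observable kind (names from [observable_kinds()]).
#' @param year_mask optional named list: for a kind, the subset of
#'   `survey_years` for which that series is available (e.g. pack-a-day
#'   counts for 2010 onwards only, as in the Australian surveys).
#' @param seed integer seed, recorded in the generated metadata.
#' @param year_zero calendar year at which model time is 0.
#' @return An object of class `survey_spec`.
#' @export
survey_spec <- function(true_params = australia_like_params(),
                        survey_years = seq(2001, 2016, by = 3),
                        sigma_by_series = c(current_smokers = 0.02,
                                            former_smokers = 0.02,
                                            pack_a_day = 0.02,
                                            past_year_quitters = 0.02),
                        year_mask = list(pack_a_day =
                                           survey_years[survey_years >= 2010]),
                        seed = 1,
                        year_zero = 2001) {
  validate_smoking_params(true_params)
  kinds <- observable_kinds()
  if (!all(kinds %in% names(sigma_by_series)))
    stop("sigma_by_series must name all four observable kinds")
  if (any(sigma_by_series < 0)) stop("sigma values must be nonnegative")
  if (any(diff(survey_years) <= 0))
    stop("survey years must be strictly increasing")
  if (length(year_mask) && !all(names(year_mask) %in% kinds))
    stop("year_mask names must be observable kinds")
  for (k in names(year_mask))
    if (!all(year_mask[[k]] %in% survey_years))
      stop("year_mask years must be a subset of survey_years")
  structure(list(true_params = true_params, survey_years = survey_years,
                 sigma_by_series = sigma_by_series[kinds],
                 year_mask = year_mask, seed = as.integer(seed),
                 year_zero = year_zero),
            class = "survey_spec")
}

# the (year, kind) layout implied by a spec
.spec_layout <- function(spec) {
  out <- do.call(rbind, lapply(observable_kinds(), function(k) {
    yrs <- if (k %in% names(spec$year_mask)) spec$year_mask[[k]]
           else spec$survey_years
    if (!length(yrs)) return(NULL)
    data.frame(year = yrs, kind = k, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic survey data set
#'
#' Simulates the model at the true parameters, maps the trajectory to
#' the four expected count series with [predict_observables()], then for
#' each observation draws a latent deviate `epsilon ~ N(0, sigma^2)` and
#' a count `y ~ Poisson(m * exp(epsilon))` — exactly the statistical
#' structure the calibration likelihood assumes.
#'
#' @param spec a [survey_spec()].
#' @return A survey data frame (columns `year`, `kind`, `count`) with a
#'   `metadata` attribute recording the true parameters, sigmas, the
#'   expected counts `m`, the drawn `epsilon`, and the seed — enough to
#'   regenerate the data set exactly.
#' @examples
#' d <- generate_survey_data(survey_spec(seed = 7))
#' head(d)
#' @export
generate_survey_data <- function(spec) {
  stopifnot(inherits(spec, "survey_spec"))
  layout <- .spec_layout(spec)
  t_max <- max(survey_time(layout$year, spec$year_zero))
  traj <- simulate_smoking(spec$true_params, horizon = t_max + 1.5,
                           grid_step = 0.05, from = -1)
  mm <- predict_observables(traj, spec$true_params, layout,
                            year_zero = spec$year_zero)
  if (any(mm$m <= 0))
    stop("degenerate expected count: the model predicts zero persons ",
         "for an observed series")
  set.seed(spec$seed)
  eps <- stats::rnorm(nrow(mm), 0, spec$sigma_by_series[mm$kind])
  counts <- stats::rpois(nrow(mm), mm$m * exp(eps))
  out <- data.frame(year = mm$year, kind = mm$kind, count = counts)
  attr(out, "metadata") <- list(true_params = spec$true_params,
                                sigma_by_series = spec$sigma_by_series,
                                m = mm$m, epsilon = eps, seed = spec$seed,
                                year_zero = spec$year_zero)
  validate_survey_data(out)
  out
}

#' Parameter-recovery experiment
#'
#' The acceptance surface for the calibration stage: repeatedly generate
#' a synthetic survey data set at known true parameters, fit the model,
#' and record per-parameter bias, 95%-interval coverage and the
#' convergence flag. Non-convergent fits are kept and flagged, never
#' dropped.
#'
#' @param spec a [survey_spec()] describing the generating conditions;
#'   replicate `i` uses seed `spec$seed + i - 1` for both generation and
#'   fitting.
#' @param n_reps number of replicates.
#' @param chains,iter,warmup sampler configuration per fit (see
#'   [fit_smoking_model()]).
#' @param params_to_track parameters whose recovery is recorded
#'   (default: the four trend rates).
#' @return An object of class `recovery_report`: a per-replicate,
#'   per-parameter data frame (`true`, `median`, `q2.5`, `q97.5`,
#'   `bias`, `covered`, `converged`) with an aggregate `summary`
#'   attribute (coverage and sign-agreement rates per parameter).
#' @export
recovery_experiment <- function(spec, n_reps = 20,
                                chains = 4, iter = 1500, warmup = 3000,
                                params_to_track = c("delta_u", "delta_v",
                                                    "delta_c", "delta_r")) {
  stopifnot(inherits(spec, "survey_spec"), n_reps >= 1)
  tp <- spec$true_params
  truth <- c(delta_u = tp$delta_u, delta_v = tp$delta_v,
             delta_c = tp$delta_c, delta_r = tp$delta_r,
             u0 = tp$u0, v0 = tp$v0, c0 = tp$c0, r0 = tp$r0,
             C0 = tp$L0 + tp$H0, F0 = tp$F0,
             q0 = tp$H0 / (tp$L0 + tp$H0))
  fixed <- default_fixed(P0 = tp$P0, g0 = tp$g0, delta_g = tp$delta_g,
                         mu = tp$mu, zeta = tp$zeta, eta = tp$eta,
                         lam = tp$lam)
  rows <- list()
  for (rep in seq_len(n_reps)) {
    rspec <- spec
    rspec$seed <- spec$seed + rep - 1L
    d <- generate_survey_data(rspec)
    fit <- suppressWarnings(
      fit_smoking_model(d, fixed = fixed, chains = chains, iter = iter,
                        warmup = warmup, seed = rspec$seed,
                        year_zero = spec$year_zero))
    sm <- summarize_posterior(fit, params = params_to_track)
    rows[[rep]] <- data.frame(
      replicate = rep, parameter = sm$parameter,
      true = unname(truth[sm$parameter]),
      median = sm$median, q2.5 = sm$q2.5, q97.5 = sm$q97.5,
      bias = sm$median - unname(truth[sm$parameter]),
      covered = sm$q2.5 <= truth[sm$parameter] &
                truth[sm$parameter] <= sm$q97.5,
      sign_match = sign(sm$median) == sign(truth[sm$parameter]),
      converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  agg <- do.call(rbind, lapply(split(out, out$parameter), function(g)
    data.frame(parameter = g$parameter[1L],
               coverage = mean(g$covered),
               sign_rate = mean(g$sign_match),
               mean_bias = mean(g$bias),
               n_converged = sum(g$converged),
               n_reps = nrow(g))))
  rownames(agg) <- NULL
  structure(out, class = c("recovery_report", "data.frame"),
            summary = agg)
}

#' @export
print.recovery_report <- function(x, ...) {
  agg <- attr(x, "summary")
  if (is.null(agg) || is.null(x$converged)) {  # subset lost the attributes
    print.data.frame(x, ...)
    return(invisible(x))
  }
  cat(sprintf("<recovery_report> %d replicates\n", max(x$replicate)))
  print(agg, row.names = FALSE)
  if (any(!x$converged))
    cat(sprintf("note: %d of %d fits flagged non-converged (kept)\n",
                sum(!x$converged[!duplicated(x$replicate)]),
                max(x$replicate)))
  invisible(x)
}

#' Write a generated data set and its regeneration metadata
#'
#' Writes the survey CSV alongside a YAML sidecar holding the true
#' parameters, sigmas and seed, from which [generate_survey_data()]
#' reproduces the CSV exactly.
#'
#' @param data a data set from [generate_survey_data()].
#' @param path CSV output path; the sidecar is written to
#'   `<path>.meta.yaml`.
#' @return `path`, invisibly.
#' @export
write_synthetic_dataset <- function(data, path) {
  md <- attr(data, "metadata")
  if (is.null(md)) stop("data carries no generation metadata")
  write_survey_csv(data, path)
  yaml::write_yaml(list(true_params = unclass(md$true_params),
                        sigma_by_series = as.list(md$sigma_by_series),
                        seed = md$seed, year_zero = md$year_zero),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}
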