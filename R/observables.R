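#' Survey-observable kinds
#'
#' The four count series the model can be calibrated to: numbers of
#' current smokers (`L + H`), former smokers (`F`), pack-a-day smokers
#' (the heavy-dependence proxy, `H`), and past-year quitters (the
#' successful-quit flow `cL + lam*c*H` integrated over the trailing
#' year).
#'
#' @return Character vector of the four kind names.
#' @export
observable_kinds <- function() {
  c("current_smokers", "former_smokers", "pack_a_day",
    "past_year_quitters")
}

# map calendar survey years to model time: t = 0 at the start of
# `year_zero`; surveys are indexed at mid-year
survey_time <- function(year, year_zero = 2001, offset = 0.5) {
  year - year_zero + offset
}

#' Expected survey counts from a model trajectory
#'
#' Maps a simulated trajectory to the expected values `m_i(t)` of the
#' four survey observables. Stocks are read at mid-year of each survey
#' year (`t = year - year_zero + 0.5`); past-year quitters are the
#' integral of the cessation flow `c(s)L(s) + lam*c(s)H(s)` over the
#' trailing year `(t - 1, t]`, computed from the trajectory's cumulative
#' quit column. Values between grid points are obtained by cubic-spline
#' interpolation, so a reasonably fine trajectory grid should be used
#' (the default `grid_step = 0.1` of [simulate_smoking()] is ample).
#'
#' @param trajectory a `smoking_trajectory` from [simulate_smoking()];
#'   it must cover `[min(t) - 1, max(t)]` for the requested years.
#' @param params the [smoking_params()] object the trajectory was
#'   simulated with (used for `lam`; retained in the signature so the
#'   mapping is explicit about depending on model parameters).
#' @param years survey years: either a numeric vector (expanded against
#'   `kinds`) or a data frame with columns `year` and `kind` for
#'   per-series availability masks.
#' @param kinds observable kinds to predict when `years` is a vector.
#' @param year_zero calendar year at which model time is 0.
#' @return A data frame with columns `year`, `kind`, `m` (expected
#'   count, persons).
#' @examples
#' p <- smoking_params()
#' traj <- simulate_smoking(p, horizon = 6, from = -1)
#' predict_observables(traj, p, years = 2001:2004, year_zero = 2001)
#' @export
predict_observables <- function(trajectory, params, years,
                                kinds = observable_kinds(),
                                year_zero = 2001) {
  validate_smoking_params(params)
  if (is.data.frame(years)) {
    if (!all(c("year", "kind") %in% names(years)))
      stop("'years' data frame needs columns 'year' and 'kind'")
    at <- years[, c("year", "kind")]
  } else {
    kinds <- match.arg(kinds, observable_kinds(), several.ok = TRUE)
    at <- expand.grid(year = years, kind = kinds,
                      stringsAsFactors = FALSE)
  }
  if (!all(at$kind %in% observable_kinds()))
    stop("unknown observable kind: ",
         paste(setdiff(at$kind, observable_kinds()), collapse = ", "))
  tt <- survey_time(at$year, year_zero)
  lo <- ifelse(at$kind == "past_year_quitters", tt - 1, tt)
  rng <- range(trajectory$t)
  if (any(lo < rng[1L] - 1e-9) || any(tt > rng[2L] + 1e-9))
    stop(sprintf(paste0("trajectory covers t in [%g, %g] but observables ",
                        "need [%g, %g]; simulate with 'from' one year ",
                        "before the first survey"),
                 rng[1L], rng[2L], min(lo), max(tt)))
  fL <- stats::splinefun(trajectory$t, trajectory$L)
  fH <- stats::splinefun(trajectory$t, trajectory$H)
  fF <- stats::splinefun(trajectory$t, trajectory$F)
  fQ <- stats::splinefun(trajectory$t, trajectory$Qcum)
  m <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    m[i] <- switch(at$kind[i],
      current_smokers = fL(tt[i]) + fH(tt[i]),
      former_smokers = fF(tt[i]),
      pack_a_day = fH(tt[i]),
      past_year_quitters = fQ(tt[i]) - fQ(tt[i] - 1))
  }
  data.frame(year = at$year, kind = at$kind, m = m)
}

#' Overdispersed-Poisson log-likelihood of survey counts
#'
#' Conditional on the latent deviates, each observed count `y` is
#' Poisson with mean `m * exp(epsilon)`, where `epsilon ~ N(0, sigma^2)`
#' is the per-observation lognormal overdispersion deviate; deviations
#' are independent, so the total log-likelihood is the sum of the
#' Poisson log-masses. With `sigma = 0` (hence `epsilon = 0`) this is
#' the plain Poisson likelihood. The Gaussian prior on `epsilon` is
#' *not* included here: this is the conditional likelihood used inside
#' the sampler, which treats the deviates as auxiliary parameters.
#'
#' @param observed data frame with columns `year`, `kind`, `count`
#'   (nonnegative integer counts), as from [read_survey_csv()].
#' @param m expected counts: either a numeric vector aligned with the
#'   rows of `observed`, or a data frame from [predict_observables()]
#'   (matched on `year` and `kind`).
#' @param epsilon latent deviates, one per observation (recycled scalar
#'   allowed; default 0).
#' @return The total log-likelihood (scalar).
#' @examples
#' obs <- data.frame(year = 2001, kind = "current_smokers", count = 3)
#' log_likelihood(obs, m = 3)  # log(3^3 e^-3 / 3!)
#' @export
log_likelihood <- function(observed, m, epsilon = 0) {
  validate_survey_data(observed)
  if (is.data.frame(m)) {
    key <- paste(observed$year, observed$kind)
    idx <- match(key, paste(m$year, m$kind))
    if (anyNA(idx))
      stop("expected counts missing for some observations")
    m <- m$m[idx]
  }
  if (length(m) != nrow(observed))
    stop("'m' must supply one expected count per observation")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("expected counts must be positive and finite")
  epsilon <- rep_len(epsilon, nrow(observed))
  sum(stats::dpois(observed$count, lambda = m * exp(epsilon), log = TRUE))
}

#' Validate a survey count data set
#'
#' Checks the survey CSV contract: columns `year`, `kind`, `count`;
#' kinds among [observable_kinds()]; counts nonnegative integers; years
#' strictly increasing within each series.
#'
#' @param df a data frame of survey observations.
#' @return `df`, invisibly, if valid.
#' @export
validate_survey_data <- function(df) {
  if (!is.data.frame(df) || !all(c("year", "kind", "count") %in% names(df)))
    stop("survey data must have columns year, kind, count")
  if (!all(df$kind %in% observable_kinds()))
    stop("unknown observable kind: ",
         paste(unique(setdiff(df$kind, observable_kinds())), collapse = ", "))
  if (any(!is.finite(df$count)) || any(df$count < 0) ||
      any(df$count != round(df$count)))
    stop("counts must be nonnegative integers")
  for (k in unique(df$kind)) {
    yrs <- df$year[df$kind == k]
    if (any(diff(yrs) <= 0))
      stop("survey years must be strictly increasing within series ", k)
  }
  invisible(df)
}

#' Read / write survey count series
#'
#' Survey data CSV dialect: columns `year`, `kind`, `count`, one row per
#' observation, with `kind` one of [observable_kinds()].
#'
#' @param path file path.
#' @return `read_survey_csv()` returns the validated data frame;
#'   `write_survey_csv()` returns `path` invisibly.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_survey_data(df)
  df
}

#' @rdname read_survey_csv
#' @param df a validated survey data frame.
#' @export
write_survey_csv <- function(df, path) {
  validate_survey_data(df)
  utils::write.csv(df[, c("year", "kind", "count")], path,
                   row.names = FALSE)
  invisible(path)
}
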