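---
title: "Modelling population-level nicotine dependence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling population-level nicotine dependence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokedyn)
```

## The scientific question

The *hardening hypothesis* holds that as tobacco control drives
less-dependent smokers to quit, the remaining smoking population becomes
increasingly dominated by heavily dependent smokers who are less
responsive to population-level measures — so that continued progress
would require a shift towards intensive individual treatment. Whether
hardening actually occurs depends on the joint dynamics of initiation,
progression to heavy smoking, cessation, relapse and mortality, not on
cessation alone. `smokedyn` implements a minimal system-dynamics model
of these flows, the perturbation experiments that probe the hypothesis,
and a Bayesian calibration pathway that confronts the model with survey
count series.

## The model

Three stocks evolve in a total population $P$: less-dependent smokers
$L$, heavily dependent smokers $H$, and former smokers $F$; never
smokers are the residual $N = P - L - H - F$. The flows are

$$
\begin{aligned}
\dot L &= uN + rF - (v + c + \mu)\,L,\\
\dot H &= vL - (\lambda c + \zeta\mu)\,H,\\
\dot F &= cL + \lambda c H - (r + \eta\mu)\,F,\\
\dot P &= gP,
\end{aligned}
$$

where $u$, $v$, $c$, $r$ are per-capita rates (1/year) of initiation,
progression to heavy dependence, cessation of less-dependent smokers,
and relapse; $\lambda \in (0,1)$ is the cessation-rate ratio of heavily
dependent smokers (they quit more slowly); and mortality is $\mu$ for
less-dependent, $\zeta\mu$ ($\zeta > 1$) for heavily dependent, and
$\eta\mu$ ($\eta < 1$) for former smokers. New smokers enter the
less-dependent stock; relapsers return to it, on the assumption that
former smokers have been abstinent long enough (about a month or more)
that pre-quit dependence no longer predicts relapse.

Policy-driven change is modelled as exponential trends: each rate obeys
$x(t) = x_0 e^{\delta_x t}$, with $\delta_x$ the *fractional increase
rate* per year (negative values give decay). The population growth rate
declines as $g(t) = g_0 e^{-\delta_g t}$.

The headline summary is the heavy-dependence fraction
$q = H/(L+H)$: *hardening* is a rise in $q$, *softening* a decline.
When the initiation rate is positive, the model has the closed-form
equilibrium

$$q^\* = \frac{v}{v + \lambda c + \zeta\mu},$$

which depends on neither $u$ nor $r$. Under the baseline
parameterization ($v = 0.2$, $\lambda = 0.4$, $c = 0.4$, $\zeta = 1.5$,
$\mu = 0.02$) this is $0.2/0.39 = 51.3\%$:

```{r equilibrium}
p <- smoking_params()
equilibrium_q(p)
tail(simulate_smoking(p, horizon = 1000, grid_step = 1)$q, 1)
```

Because $q^\*$ is *decreasing* in $c$, any sustained intervention that
raises the cessation rate ultimately softens the population — the core
result the step-change experiments exhibit, and the reason the
hardening hypothesis fails in this model class.

### Population accounting

The model assigns no explicit mortality to never smokers, yet the total
population must stay constant when $g = 0$ even though the smoking
stocks lose people to death. We resolve this by letting $P$ evolve only
through $\dot P = gP$ and defining $N$ as the residual: deaths from
$L$, $H$, $F$ are implicitly replaced within the never-smoker pool.
This reproduces the constant-population baseline exactly and leaves the
$L$/$H$/$F$ dynamics — the basis of every reported quantity —
untouched. The alternatives (explicit never-smoker mortality plus
matching births) would add parameters the observables cannot identify.

## Numerical integration

`simulate_smoking()` integrates with `deSolve::lsoda` (adaptive
stiff/non-stiff switching), relative tolerance $10^{-8}$ and absolute
tolerance $10^{-6}$ persons — far below survey noise. Time-varying
rates are evaluated continuously inside the solver, not discretised
annually, because the $\delta$ formulation is a differential statement.
Trajectories may extend to negative times (integration backwards from
the anchor $t=0$) so that trailing observation windows before the first
survey are covered. Invariants (nonnegative stocks and residual) are
checked after integration with tolerance $10^{-6} P_0$; `q` is reported
as missing, not zero, where $L + H = 0$.

The calibration hot path uses a fixed-step classical Runge–Kutta
integrator (step 0.025 years) written in C++, because an MCMC run
evaluates tens of thousands of trajectories. The two routes are
cross-checked against each other in the test suite at $10^{-7}$
relative tolerance, and the stock derivatives are separately verified
against hand-computed flow sums.

A cumulative cessation state $Q(t) = \int_0^t (cL + \lambda cH)\,ds$
is carried alongside the stocks so that the past-year-quitters
observable is an exact integral, $Q(t) - Q(t-1)$, rather than a
quadrature bolted on afterwards.

## Step-change experiments

`run_step_experiment()` equilibrates the model (1000 years by default;
settling is verified as $|dq/dt| < 10^{-8}$/yr *and* agreement with
$q^\*$ within $10^{-4}$, and failure to settle is an error, not a
warning), restarts the clock, and applies an instantaneous, sustained
multiplier to one of $u$, $v$, $c$, $r$ at `onset` (default year 10).
The integration is split at the onset so the solver never steps across
the discontinuity; stocks are continuous there by construction.

The experiment grid mirrors the standard design: $u$, $v$, $r$ reduced
by 10/20/30% and increased by 10%; $c$ increased by 10/20/30% and
reduced by 10%. The qualitative signatures, which the acceptance tests
assert, are:

* cessation increases cause a *transient* rise in $q$ followed by a
  decline to a strictly lower equilibrium, with the eventual decrease
  substantially exceeding the transient rise;
* initiation or relapse reductions raise $q$ temporarily, but $q$
  returns to its original equilibrium (which does not depend on $u$ or
  $r$); larger reductions give larger transient peaks, and increases
  give mirror-image temporary dips;
* progression reductions lower $q$ monotonically, with no upward
  transient.

One numerical nuance: after a progression step the approach to the new
equilibrium is very slightly oscillatory (the relevant eigenvalues have
a small imaginary part), producing an undershoot of order $10^{-4}$ in
$q$ before the final relaxation — invisible at plotting scale. The
monotonicity check therefore requires strict decline only until $q$ is
within $10^{-3}$ of the new equilibrium. "New equilibrium reached" is
operationalised as $|q(t) - q^\*| < 10^{-4}$ throughout; the default
200-year horizon lets every transient on the grid resolve fully.

## Observation model

Four survey count series map onto the model:
current smokers $\to L + H$; former smokers $\to F$; pack-a-day
smokers (20+ cigarettes/day, the heavy-dependence proxy) $\to H$; and
past-year quitters $\to \int_{t-1}^{t} (cL + \lambda cH)\,ds$. The
quitters mapping is our own convention — the successful-quit flow
accumulated over the trailing year — justified by the model's relapse
assumption that entry into $F$ already implies roughly a month's
abstinence. Surveys are indexed at mid-year: calendar year $y$ maps to
model time $t = y - y_0 + 0.5$ with $y_0 = 2001$ by default.

Counts are treated as overdispersed Poisson: conditional on a latent
deviate $\varepsilon_i(t) \sim N(0, \sigma_i^2)$,

$$y_i(t) \mid \theta, \varepsilon_i(t)
  \sim \text{Poisson}\!\left(m_i(t,\theta)\, e^{\varepsilon_i(t)}\right),$$

independently across series and years, with one scale $\sigma_i$ per
series (the subscript is per-series, not shared). With $\sigma_i = 0$
this collapses to plain Poisson. The lognormal multiplier is the
model's entire accommodation of survey error; design effects and
weighting are deliberately out of scope. The counts are
population-scale estimates (persons aged 14+), not respondent counts,
and the synthetic generator emulates that scale.

## Bayesian calibration

`fit_smoking_model()` samples the posterior of the four trend rates
$\delta_u, \delta_v, \delta_c, \delta_r$, the initial rates $u_0, v_0,
c_0, r_0$, the initial numbers of current ($C_0$) and former ($F_0$)
smokers, the initial heavy fraction $q_0$ (so $L_0 = (1-q_0)C_0$,
$H_0 = q_0 C_0$), the per-series $\sigma_i$, and the latent
$\varepsilon$. Fixed and never sampled: $\mu, \zeta, \eta, \lambda,
P_0, g_0, \delta_g$ — the fixed/free split is explicit in the fit
object. Default priors (every one overridable, and recorded in the
returned object):

| parameter | prior | rationale |
|---|---|---|
| each $\delta$ | normal(0, 0.05) | per-year fractional changes of a few percent |
| $u_0, v_0, c_0, r_0$ | lognormal, centred at baseline values, log-SD 1 | weakly informative, positive |
| $C_0$, $F_0$ | lognormal, centred at 20% / 25% of $P_0$, log-SD 1 | typical prevalence scales |
| $q_0$ | uniform(0, 1) | uninformative on a fraction |
| each $\sigma_i$ | half-normal(0, 0.5) | survey error well under $e^{0.5}$-fold |

These are package defaults chosen for the synthetic studies; they are
not asserted to be the priors of any particular published analysis.

### Sampler

The sampler is an adaptive Metropolis-within-Gibbs scheme written for
this posterior:

1. **Structural block** (11 parameters, transformed to an unconstrained
   scale: raw $\delta$'s, log rates and stocks, logit $q_0$): a
   multivariate random-walk proposal whose covariance is adapted during
   warmup from the chain history, mixed 50/50 with
   differential-evolution jumps along differences of two random warmup
   states. The proposal distribution is frozen when warmup ends.
2. **Residual preservation.** Survey counts in the millions make the
   Poisson factor a constraint of relative precision
   $\sim 1/\sqrt{y}$, which glues $\theta$ to $\varepsilon$ and stalls
   a naive sampler. The structural proposal therefore shifts every
   deviate by $\varepsilon' = \varepsilon + \log m - \log m'$, leaving
   each Poisson mean $m e^{\varepsilon}$ — and hence the whole
   conditional likelihood — invariant (the map is a translation, so the
   Jacobian is 1). The acceptance ratio then involves only the
   structural prior and the Gaussian prior on the deviates. The
   deviates remain genuine sampled parameters.
3. **Deviates and scales**: vectorised univariate random-walk updates
   for all $\varepsilon$ (conditionally independent given $m$) and for
   each $\log\sigma_i$, with per-coordinate acceptance-rate adaptation
   (target 0.44) during warmup.

Convergence is summarised by the split-chain potential scale reduction
factor; a fit with any structural value $\ge 1.01$ is returned with
`converged = FALSE` and a warning — flagged, never silent. Identical
seed and configuration reproduce draws exactly. Sampler correctness is
validated by prior-only runs (likelihood switched off) recovering the
prior marginals, and by recovery of known truths from synthetic data.

Defaults are 4 chains × 2000 kept draws (8000 total, the convention for
the headline posterior summaries) after 3000 adaptation iterations.
This posterior has long, weakly identified ridges (notably
$q_0$–$v_0$–$c_0$ when the pack-a-day series is short), and the default
budget often lands around split-Rhat 1.05–1.2 — reported honestly via
the flag; doubling the budget brings it near 1.01–1.05. Posterior
medians and 95% intervals are robust to this in the recovery
experiments, which is the calibration property the package actually
claims.

`posterior_predictive()` reruns the deterministic model for randomly
chosen posterior draws (1000 by default, with replacement if more are
requested than exist — recorded in the result) and returns pointwise
quantile bands for current/past prevalence, $q$, and the per-capita
cessation rate $(cL + \lambda cH)/(L+H)$.

## Synthetic surveys and the recovery experiment

`generate_survey_data()` inverts the observation model exactly:
simulate the trajectory at known true parameters, evaluate the four
expected-count series, draw $\varepsilon \sim N(0, \sigma_i^2)$ and
$y \sim \text{Poisson}(m e^{\varepsilon})$. The metadata attribute
(truth, $\sigma$, seed) regenerates a data set byte-for-byte.

The default truth, `australia_like_params()`, represents a mature
tobacco-control environment on a 20-million population aged 14+:
initial prevalence 23.1% with 52.1% of smokers heavily dependent,
former-smoker prevalence 25%, baseline behaviour rates, population
growth 1.2%/year, and negative trends on all four rates. The trend
magnitudes are not free knobs: $\delta_v$ and $\delta_c$ were solved
(with $\delta_u = -0.02$, $\delta_r = -0.03$ held at plausible values)
so that the generating trajectory reproduces the reported Australian
declines over 2001–2016 — current prevalence falling to 14.6% and the
heavy fraction to 36.9% by mid-2016 — giving $\delta_v = -0.082$ and
$\delta_c = -0.024$. Surveys are triennial (2001–2016, six waves), with
the pack-a-day series available from 2010 only, matching the
availability the real calibration faced; $\sigma_i = 0.02$ for all
series, the relative-error scale of national household-survey count
estimates.

```{r australia, eval = FALSE}
d <- generate_survey_data(survey_spec(seed = 1))
fit <- fit_smoking_model(d, fixed = default_fixed(P0 = 2e7, g0 = 0.012),
                         seed = 1)
summarize_posterior(fit)
```

`recovery_experiment()` is the acceptance surface for the whole
inference stage: replicate generate → fit → summarise runs, recording
per-parameter bias, 95%-interval coverage, sign agreement of the
posterior median, and the convergence flag (non-convergent fits are
kept and flagged, never dropped). Under the default conditions, 20
replicates give interval coverage of each $\delta$ of at least 80% and
the correct (negative) median sign for $\delta_v$, $\delta_c$,
$\delta_r$ in at least 80% of replicates — the test suite asserts
exactly this.

What the generator does *not* emulate: survey weighting and design
effects, nonresponse, demographic shifts within the smoking population,
social-network effects, and disease-feedback on cessation. Passing
recovery therefore demonstrates that the *inference machinery* is
calibrated for data with the assumed statistical structure, not that
the model is a complete description of real survey data.

## Problem sizes and numerical choices

The shipped analyses use: 1000-year equilibration runs (grid step 1),
200-year step-change horizons (grid step 0.25), trajectory grids of
0.05 years for observable prediction, RK4 step 0.025 years in the
likelihood, 20 recovery replicates at 4 chains × (3000 warmup + 1500
kept) each, and 1000 posterior-predictive simulations. Ties and
degenerate inputs: a multiplier must be strictly positive; an unknown
target rate, a trajectory that does not cover a requested observation
window, a nonpositive expected count under an observed point, and
non-integer or negative counts are all hard errors.

## Known limitations

* Homogeneous population: no age, sex or socioeconomic structure, and
  no migration. The model's $q$ is a population average.
* Exponential rate trends exclude time-varying intervention effects and
  policy interactions; the trend rates are constants of the fit.
* The pack-a-day proxy equates consumption with dependence; the model
  inherits whatever bias that proxy carries.
* The equilibrium $q^\*$ is verified numerically to be stable across
  wide parameter ranges; no formal stability proof is attempted here.
* With sparse series the posterior is prior-sensitive in $u_0$ and
  $\delta_u$ (initiation is weakly identified by adult smoking counts);
  conclusions about those parameters should lean on the intervals, not
  the medians.
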