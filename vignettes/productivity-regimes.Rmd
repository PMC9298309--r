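---
title: "Modelling nonstationary salmonid productivity regimes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nonstationary salmonid productivity regimes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(salmonregimes)
```

This vignette is the package's account of its statistical methods: the model
and its assumptions, the parameters that matter, the synthetic-data generator
that stands in for a real monitored watershed, the numerical design of the
sampler, and the limitations a user should understand before trusting output
on real data.

## The scientific problem

Anadromous salmonids complete a life cycle that spans freshwater rearing and
one or more years at sea, so a brood year's productivity integrates the state
of two ecosystems. Long fence-count monitoring programs yield, per species,
an annual table of spawners `S_t` and the recruits `R_t` those spawners
produced (smolt out-migrants for stream-rearing species; returning adults two
years later for Pink Salmon, which goes to sea as fry). The central quantity
is recruitment productivity `ln(R_t/S_t)`. The question the package answers:
have the processes generating productivity shifted persistently — a regime
shift — and which measured environmental changes are associated with the
shifts, separately from ordinary density dependence and noise?

## The community model

For a community of `d` species observed over brood years `t = 1..T`:

* **Observation equation.** The `d`-vector of observed `ln(R_t/S_t)` is
  multivariate normal around the linearized Ricker mean
  `ln(alpha_{t,i}) - beta_i S_{t,i} + delta_i' x_{t,i}` with full covariance
  `Sigma_O`. Off-diagonal observation covariance captures synchrony in
  measurement and shared fast environmental noise.
* **Process equation.** The vector `ln(alpha_t)` of log intrinsic
  productivities follows a multivariate random walk with covariance
  `Sigma_P`. Its level is the productivity regime; correlated innovations
  let regimes move together across species.
* **Variants.** `build_variant()` produces the nested structures:
  `stationary` (constant `alpha`, `beta`), `alpha_varying` (the default),
  `beta_varying`, and `both` (random walks on both parameters, the
  density-dependence walk entering the observation loading). The stationary
  model is exactly the `alpha_varying` model with all innovations zero, a
  nesting verified to machine precision in the tests. Variants are compared
  by PSIS-LOO on per-year observation log-likelihoods.

Assumptions worth stating plainly: spawner counts are treated as exogenous
and error-free (the universal stock–recruitment practice; see Limitations);
covariate effects are linear on the log scale and constant in time;
recruitment noise is Gaussian on the log scale; the random walk is the only
nonstationary mechanism, so gradual trends and step changes are both
expressed as accumulated innovations.

## The Steelhead life cycle

The integrated submodel links three linked regressions, each with its own
random-walk intercept and Gaussian observation error:

* logit marine survival `logit(m_t) = m0_t + delta_m' x_mt`, with observed
  survival derived as returns-per-smolt on the empirical logit (a half-count
  continuity correction handles cohorts with zero observed returns, since
  `logit(0)` is undefined). The first cohort's survival has no observed
  antecedent and enters as missing data under the vague normal initial-state
  prior.
* adult female returns `S_t = S0_t + dS1 m_t + dS2 F_t` on the identity
  link, exactly as the linear form is written. An identity link can predict
  negative returns at extreme inputs; rather than silently switching links,
  fitted models count negative expected-return draws and report the count
  (`fit$neg_pred`).
* median run date `T_t = T0_t + dTS ln(S_t) + delta_T' x_Tt` in day-of-year
  units counted from January 1, with log-linear density dependence of timing
  on spawner abundance.

Years with a missing adult count contribute no returns term and no timing
term (there `ln S_t` is undefined); survival observations are dropped only
where themselves missing. Timing covariates are climate windows anchored on
the run: mean air temperature and total rainfall over the 14 days before the
median upstream migration; smolt-production covariates use the 30 days after
it (`window_covariate()`).

## Covariate construction

* **Brood-year lagging.** Annual environmental series are matched to brood
  years with the weighted average of the species' proportions-at-age. The
  convention, documented and tested explicitly: a brood-year `t` cohort with
  freshwater age `a >= 1` experiences years `t .. t+a-1` (egg deposition
  through the year before smolt out-migration; fry migrants, `a = 0`,
  experience year `t` only), and the covariate is averaged over that span;
  the marine phase spans out-migration through return inclusive, weighted by
  the product of freshwater and marine proportions-at-age. For a cohort of
  smolts leaving in year `Y`, the freshwater conditions are therefore drawn
  from the years before `Y`, never from the out-migration year itself.
* **Cumulative logging.** Forestry impacts integrate over decades, so the
  logging index at year `t` is the total area cut over a sliding window
  (default 15 years, configurable over the 5–30-year range used in
  sensitivity analyses). Years whose window would reach before the start of
  the series are not returned — the series must be extended backwards with
  recorded pre-series harvest, never silently zero-filled, which would
  understate early cumulative harvest.
* **Seal exposure.** A cohort is exposed to pinniped predation in its
  out-migration year and again in its return year, so its exposure is the
  sum of seal densities in those two years; fry migrants below the predation
  size window count only the return year (`adult_only = TRUE`).
* **Collinear ocean indices.** Seal density and North Pacific salmon
  abundance trend together; they are collapsed into two principal-component
  scores. Sign convention: the first axis ("ocean interactions") loads
  positively on the first input; the second axis loads positively on the
  first input and negatively on the second. The PCA is computed on
  standardized series, so neither index dominates the axes by scale alone.
* **Standardization.** All covariates are centered and scaled to unit
  variance using the population SD (denominator `n`), so effect sizes are
  directly comparable across covariates; the constants are stored for exact
  inversion. Binary indicators (nutrient enrichment) are standardized like
  continuous covariates, with the raw coding preserved upstream.
* **Screening.** `vif_screen()` reports `1/(1 - R^2_j)` per column and flags
  values above 4, the usual cut for ecological regressions; perfectly
  collinear columns are reported as infinite, not hidden behind an error.

## Missing data

Covariate series are imputed by a dynamic factor analysis: a small number of
shared latent random-walk trends with lower-triangular loadings (positive
diagonal, unit process variance — the standard identifiability convention)
and diagonal observation error, fitted by EM with a Kalman smoother E-step.
The EM log-likelihood is non-decreasing (asserted at every iteration) and
convergence is declared at a relative improvement below `1e-6` within 2,000
iterations; non-convergence is a warning, never silent. Counts should be
`log(x+1)`-transformed before the DFA. The default is two trends for a
covariate block; `dfa_aicc()` supports a sweep when the choice matters.
Smoothed expectations replace only missing cells; observed cells are never
altered, and imputation flags are returned alongside.

Missing recruitment observations, by contrast, are handled *inside* the
community sampler by exact data augmentation (drawn each sweep from their
conditional normal given the observed species that year), so their
uncertainty propagates into every posterior. DFA pre-filling of brood tables
remains available but is deliberately not the default for the likelihood:
point-imputed responses understate uncertainty.

## Priors and sampler design

The model is conditionally linear-Gaussian, which the sampler exploits
end-to-end:

1. **Coefficients** (constant intercepts, density dependence, covariate
   effects) are drawn from their Gaussian full conditional with the latent
   paths integrated out, computed by an augmented Kalman filter: the filter
   is linear in its observation input, so the innovations of each regressor
   column are filtered alongside the data with shared gains, and the GLS
   precision accumulates from them. Marginalizing the states is essential:
   slow-trend covariates (cumulative logging, seal recovery) are nearly
   collinear with a random-walk intercept, and alternating conditional draws
   of states and coefficients mixes arbitrarily slowly in exactly that
   direction.
2. **Latent paths** are then drawn exactly by forward-filter
   backward-sampling given the coefficients.
3. **Covariances** have inverse-Wishart conjugate updates; scalar variances
   in the life-cycle model have inverse-gamma updates.
4. **Positivity of density dependence** (`beta >= 0`, a half-normal prior on
   the scaled-spawner axis) is enforced by rejection on the joint Gaussian
   coefficient draw, with a truncated coordinate-Gibbs fallback if rejection
   repeatedly fails.
5. The Steelhead returns coefficient `dS1` multiplies a latent state, so its
   state-marginalized conditional is not Gaussian; it is updated by slice
   sampling on the marginal likelihood evaluated by the Kalman filter.

Priors are weakly informative defaults, all overridable via
`community_priors()` / `steelhead_priors()`: `Normal(0, 5^2)` coefficients on
standardized covariates (and `delta` chains start at 0); half-`Normal(0, 5^2)`
density dependence after spawners are scaled by their per-species maximum
(`beta` is reported back on the raw scale); `Normal(0, 5^2)` initial
intrinsic productivity; inverse-Wishart covariance priors with `nu0 = d + 1`
degrees of freedom and scale `0.05 I`. The covariance prior is chosen so the
posterior mean of each variance is essentially its maximum-likelihood value
(`(scale + SS) / T`), i.e. minimal shrinkage whatever the data's scale; a
calibration study with exogenous spawners confirms nominal 80% interval
coverage for the regression parameters under these settings. Inverse-Wishart
replaces the half-Normal + LKJ combination a gradient-based sampler would
use, because it keeps the Gibbs sampler exactly conjugate; both encode weak
information on the same quantities.

All randomness flows through R's RNG, so any fit is bit-reproducible under
`seed`, chains included. The desk profile (2 chains x 1,500 iterations, 50%
warmup) is sized for tests and exploration; production inference should use
the production profile (6 x 10,000, 30,000 retained draws) and verify
PSRF < 1.1 and ESS > 1,000 per parameter with `convergence_report()`.

## Diagnostics, model comparison, and predictive checks

PSRF is the split-chain Gelman–Rubin statistic; ESS deflates the pooled draw
count by the integrated autocorrelation time with Geyer's initial-positive-
sequence cutoff. PSIS-LOO follows the Pareto-smoothed importance-sampling
construction (generalized-Pareto tail fit by the Zhang–Stephens profile
posterior with the usual weak shape regularization), reporting pointwise
elpd, its SE, and Pareto-k diagnostics; observations with `k > 0.7` are
reported, never silently refit. These components are validated in the test
suite against an AR(0.99) fixture, constructed non-convergent chains, exact
leave-one-out refits of a conjugate model, and simulated generalized-Pareto
tails.

Posterior predictive checks simulate replicate observations per posterior
draw and score central-interval coverage. Two behaviours of state-space PPCs
deserve emphasis, both documented by the acceptance tests: scored against
the *fitted* data, a model with a per-year latent path over-covers (the path
absorbs part of each residual), and scored against a *fresh* replicate at a
fixed truth it under-covers somewhat, because the process/observation
variance partition is weakly identified at `T = 40` (the posterior
concentrates on the true partition as `T` grows). Interval calibration is
therefore checked quantitatively on the stationary variant, where in-sample
coverage is clean, while the state model's PPC is used for what it is good
at: detecting misspecification (an injected mean shift collapses coverage).

## Posterior summaries

`percent_change()` reports regime changes in intrinsic productivity between
two years. The default scale is natural `alpha` (recruits per spawner at low
density is the interpretable quantity); the `ln_alpha` scale is available
explicitly, and because a ratio of log-scale values is ill-defined when the
path crosses zero, such draws are counted and flagged rather than hidden.
`logging_marginal_effect()` converts a coefficient and a standardized
covariate shift into an all-else-equal percent change,
`100(exp(delta * dx) - 1)`, using the stored standardization constants and
erroring if they are absent. `regime_timing_shift()` compares within-window
means of the predicted run date between regimes; window boundaries default
to an early (1976–1990), compensatory (1991–2009), and declining (2010–)
regime but are configuration, never hard-coded — descriptive regime
boundaries are a modelling choice, not an estimate. All summaries are pure
functions of the draws (permutation-invariant, verified by tests).

## The synthetic watershed generator

`generate_dataset()` produces a complete, internally consistent dataset with
stored truth: five species with the age structures of a small coastal
watershed community (fry-migrant Pink Salmon through long-rearing Cutthroat);
40 brood years (1976–2015); covariates with the qualitative shapes of the
real system — a logging ramp reaching a plateau, a logistic seal recovery
with an exactly eightfold increase over the study years, a 2.4-fold rise in
North Pacific salmon abundance, a ~10-year ocean cycle, white-noise climate
derived from generated daily weather, and nutrient-enrichment indicator
blocks (1983–1986, 1997–2004); correlated random-walk intrinsic-productivity
paths (process SD 0.3, enough to produce visible multi-decadal regimes);
and missingness at the rates of real fence programs (10.5% of adult cohorts,
1.5% of juvenile cohorts, ~0.5% of covariate years, injected completely at
random).

Because the inference model conditions on observed spawners, the generator
must *produce* spawners: a closed demographic loop routes each brood year's
true Ricker recruits to future spawning years through the fixed
proportions-at-age and a constant generator-only marine survival.
Observation error is kept out of the demography (only true recruits
propagate), and baseline productivities are set so the deterministic
skeleton sits at realistic equilibria (hundreds to tens of thousands of
spawners by species); if a trajectory still falls below half a spawner the
community is regenerated with a warning and the attempt count is reported.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: measurement error in spawner counts themselves;
age-structure variability between years; non-Gaussian recruitment noise;
autocorrelated climate; informative (non-random) missingness; and any
feedback of density on age at migration. One structural consequence is worth
knowing: generated spawners are a deterministic function of past latent
productivity, while the fitted model treats them as exogenous — exactly the
approximation every stock–recruitment analysis makes — so frequentist
coverage of credible intervals under the full closed-loop generator runs a
few points below nominal even though the sampler itself is calibrated (the
acceptance suite measures both).

## Numerical choices and degenerate inputs

Covariance draws are guarded by symmetrization and a last-resort jitter in
the Cholesky; the truncated-normal inverse-CDF draw is floored to stay
finite in extreme tails; design matrices must be complete (impute first) and
zero-variance columns are an error naming the column; `fit_dfa()` refuses
all-missing and zero-variance series; brood tables mark `ln(R/S)` as missing
wherever either side is missing or non-positive; a species with fewer than
three observed brood years is an error. The slice sampler uses a step-out
width of 0.5 with capped expansion, ample for a standardized-covariate
coefficient. EM uses a relative log-likelihood tolerance of `1e-6`;
smoother-vs-brute-force agreement is tested to `1e-8`; analytic Ricker and
logistic oracles to `1e-10`.

## Known limitations

* Observation-error-free spawners (see above) and the resulting mild
  endogeneity of the closed-loop validation.
* The identity-link returns equation can, in principle, predict negative
  adults; the diagnostic count is reported, and a log-link variant is a
  reasonable user extension.
* `Sigma_O` and `Sigma_P` carry full correlation structure; with five
  species and 40 years these matrices are weakly identified, and the
  process/observation partition especially so — inspect `Sigma_P` posteriors
  before interpreting regime sharpness.
* PSIS-LOO here conditions on the sampled latent states (as pointwise
  log-likelihoods from state-space fits usually do), which favours flexible
  variants; it answers "does the time-varying structure predict better?"
  conditionally, not marginally.
* Regime windows for summaries are descriptive configuration; the package
  deliberately does not estimate changepoints.
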