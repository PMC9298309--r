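# salmonregimes

Bayesian multivariate state-space models for detecting and attributing
**nonstationary productivity regimes** in communities of anadromous salmonids.

Rivers of the Pacific Northwest support several co-occurring salmonid species
(Steelhead, Coho, Pink Salmon, Dolly Varden, Coastal Cutthroat) whose
brood-year recruitment is monitored for decades at counting fences. Over such
spans, recruitment productivity is rarely stationary: marine predator
recoveries, ocean competition, watershed logging, and climate all drift or
cycle, and populations can move between persistent productivity regimes. This
package is for quantitative ecologists and fisheries scientists who want to
(i) detect such regimes from stock–recruitment time series of several species
at once, (ii) attribute them to measured environmental covariates, and (iii)
link a focal species' freshwater and marine life-cycle stages in one
integrated model.

## The model

For species *i* and brood year *t*, observed recruitment productivity is the
linearized Ricker form with a time-varying intercept:

```
ln(R_t/S_t) ~ MVN( ln(alpha_t) - beta * S_t + delta' X_t ,  Sigma_O )   (observation)
ln(alpha_t) ~ MVN( ln(alpha_{t-1}) ,  Sigma_P )                          (process)
```

`ln(alpha_t)` is intrinsic productivity — log recruits per spawner at low
density — evolving as a correlated multivariate random walk across the five
species; `beta > 0` is density dependence (`1/beta` is the spawner abundance
maximizing recruitment); `delta` are effects of standardized environmental
covariates; `Sigma_O` and `Sigma_P` are full observation and process
covariance matrices. A persistent change in `ln(alpha_t)` is a productivity
regime shift; if there is none, the random-walk innovations shrink toward
zero and the model collapses to the stationary Ricker regression (the nested
variants are compared by PSIS-LOO).

An integrated Steelhead life-cycle submodel links marine survival
(`logit(m_t) = m0_t + delta_m' X_mt`), adult female returns
(`S_t = S0_t + dS1 * m_t + dS2 * F_t` for smolt cohort `F_t`), and median
upstream run timing (`T_t = T0_t + dTS * ln(S_t) + delta_T' X_Tt`), each
intercept a random walk, closing the cycle back into smolt production.

The posterior is sampled by a conjugate blocked Gibbs sampler written in
RcppArmadillo: regression coefficients are drawn from their
**state-marginalized** Gaussian conditionals via an augmented Kalman filter,
latent paths by forward-filter backward-sampling, covariances from
inverse-Wishart conditionals, and missing observations by exact data
augmentation.

Also included: covariate construction (age-structure-weighted brood-year
lagging, sliding-window cumulative logging, seal-exposure summation, PCA
collapsing of collinear ocean indices, VIF screening), dynamic factor
analysis (EM + Kalman smoother) for imputing gappy series, convergence
diagnostics (split-PSRF, ESS), PSIS-LOO model comparison, posterior
predictive checks, regime summaries, and a synthetic watershed generator
with known truth for end-to-end validation.

## Worked example

```r
library(salmonregimes)

ds  <- generate_dataset(seed = 42)                    # synthetic 5-species watershed, 1976-2015
fit <- fit_community(ds$broods, ds$designs, profile = "desk", seed = 1)
fit
#> <community_fit> alpha_varying | 5 species x 40 years | 2 chains x 1500 iter (1500 retained draws)
#> posterior mean beta:  dolly_varden=0.00281, steelhead=0.0019, cutthroat=0.00303, coho=0.000668, pink=4.32e-05

pc <- percent_change(fit, "steelhead", 1976, 1991, scale = "alpha")
#> Steelhead intrinsic productivity change 1976-1991: +263% (80% CI -34 to 601)

me <- logging_marginal_effect(fit, "steelhead", "logging", 1976, 2015)
#> Marginal effect of logging on steelhead smolts per spawner: -52% (80% CI -74 to -27)

sign_probability(fit$draws$delta[, "steelhead:logging"])["negative"]
#> 0.98

fit0 <- fit_community(ds$broods, ds$designs, variant = "stationary",
                      profile = "desk", seed = 2)
compare_variants(list(alpha_varying = fit, stationary = fit0))
#>           model elpd_loo    se elpd_diff se_diff
#> 1 alpha_varying    -47.8  7.83         0     0.0
#> 2    stationary   -183.6 13.66      -136    11.2
```

Reading the output: every species shows density dependence (`beta > 0`; e.g.
`1/beta ~ 530` spawners maximize Steelhead recruitment in this simulation);
Steelhead intrinsic productivity rose substantially between 1976 and 1991
(the posterior mean is +263% recruits-per-spawner at low density, though the
80% interval is wide at this desk sampling scale); the standardized shift in
cumulative logging between 1976 and 2015 implies, all else equal, about a
52% decline in smolts produced per spawner, with 98% posterior probability
that the logging association is negative; and leave-one-out cross-validation
decisively prefers the time-varying-productivity model over the stationary
Ricker regression (elpd difference 136 ± 11).

The desk profile (2 chains x 1,500 iterations) is for exploration and tests;
use `profile = "production"` (6 chains x 10,000, 50% warmup, 30,000 retained
draws) for production inference, and check `convergence_report(fit)`
(PSRF < 1.1, ESS > 1000).

## Package layout

- `R/covariates.R`, `R/cov-series.R` — covariate containers and construction
- `R/dfa.R` — dynamic factor analysis (EM + Kalman smoother) imputation
- `R/community-model.R` — Ricker forms, joint log density, model variants
- `R/steelhead.R` — life-cycle equations and joint density
- `src/gibbs.cpp` — blocked Gibbs samplers (FFBS, marginalized coefficients)
- `R/fit.R`, `R/diagnostics.R`, `R/loo.R` — fitting, diagnostics, PSIS-LOO
- `R/summaries.R` — regime percent changes, marginal effects, timing shifts
- `R/synthetic.R` — synthetic watershed generator with stored truth
- `vignettes/productivity-regimes.Rmd` — the methods vignette
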