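# Integrated Steelhead life-cycle submodel: logit marine survival, adult
# returns, and upstream run timing, each a linear regression around a
# random-walk intercept, linked to freshwater smolt production.

#' Logit marine survival
#'
#' `logit(m_t) = m0 + delta_m . x_m`: smolt-to-adult survival on the logit
#' scale as a linear function of marine covariates around a (possibly
#' time-varying) intercept. The survival probability is the inverse logit of
#' the returned value, hence always in (0, 1).
#'
#' @param m0 Intercept (logit scale).
#' @param delta_m Coefficient vector (may be empty).
#' @param x_m Covariate vector conformable with `delta_m`.
#' @return The logit survival; `plogis()` of it is the probability.
#' @examples
#' plogis(marine_survival(0, -1, 2)) # ~0.1192
#' @export
marine_survival <- function(m0, delta_m = numeric(0), x_m = numeric(0)) {
  if (!all(is.finite(c(m0, delta_m, x_m)))) stop("non-finite inputs")
  if (length(delta_m) != length(x_m)) stop("delta_m and x_m must be conformable")
  m0 + sum(delta_m * x_m)
}

#' Expected adult female returns
#'
#' `S_t = S0 + dS1 * m + dS2 * F`: returning adult females as a linear
#' (identity-link) function of logit marine survival `m` and the smolt cohort
#' abundance `F`. The identity link can produce negative expectations at
#' extreme inputs; fitted models count such draws as a diagnostic rather than
#' silently truncating.
#'
#' @param S0 Intercept.
#' @param d1 Effect of logit marine survival.
#' @param m Logit marine survival.
#' @param d2 Effect of smolt cohort abundance.
#' @param F_ Smolt cohort abundance (>= 0).
#' @return Expected adult females.
#' @examples
#' adult_returns(10, 5, -2, 0.01, 1000) # 10
#' @export
adult_returns <- function(S0, d1, m, d2, F_) {
  if (!all(is.finite(c(S0, d1, m, d2, F_)))) stop("non-finite inputs")
  if (any(F_ < 0)) stop("smolt abundance must be non-negative")
  S0 + d1 * m + d2 * F_
}

#' Median run date of the upstream adult migration
#'
#' `T_t = T0 + dTS * ln(S) + delta_T . x_T`: run timing (day of year, counted
#' from January 1) as a linear function of log spawner abundance (log-linear
#' density dependence of timing) and environmental covariates.
#'
#' @param T0 Intercept (day of year).
#' @param dTS Density-dependence coefficient on `ln(S)`.
#' @param S Spawner abundance (> 0).
#' @param delta_T Coefficient vector.
#' @param x_T Covariate vector.
#' @return Median run date in day-of-year units.
#' @examples
#' run_timing(120, -5, exp(2), 3, 1) # 113
#' @export
run_timing <- function(T0, dTS = 0, S = 1, delta_T = numeric(0),
                       x_T = numeric(0)) {
  if (!all(is.finite(c(T0, dTS, S, delta_T, x_T)))) stop("non-finite inputs")
  if (any(S <= 0)) stop("S must be positive for ln(S)")
  if (length(delta_T) != length(x_T)) stop("delta_T and x_T must be conformable")
  T0 + dTS * log(S) + sum(delta_T * x_T)
}

#' Random-walk path from innovations
#'
#' Cumulative-sum path `x_t = x_0 + sum(u_1..u_t)`; with zero innovations the
#' path is constant, the stationary limit of every time-varying intercept in
#' the model.
#'
#' @param x0 Initial value.
#' @param innovations Numeric vector of innovations.
#' @return Numeric vector of length `length(innovations) + 1` starting at `x0`.
#' @examples
#' random_walk_path(0, c(1, -1)) # 0 1 0
#' @export
random_walk_path <- function(x0, innovations = numeric(0)) {
  c(x0, x0 + cumsum(innovations))
}

#' Empirical logit of observed marine survival
#'
#' Observed survival is derived as returns-per-smolt; cohorts with zero
#' observed returns are handled by a half-count continuity correction
#' (`log((r + 0.5) / (F - r + 0.5))`), since `logit(0)` is undefined.
#'
#' @param returns Observed adult returns per cohort.
#' @param smolts Smolt cohort abundances.
#' @param continuity Continuity correction (default 0.5).
#' @return Empirical logit survival, `NA` where either input is missing.
#' @export
logit_survival_obs <- function(returns, smolts, continuity = 0.5) {
  out <- rep(NA_real_, length(returns))
  ok <- !is.na(returns) & !is.na(smolts) & smolts > 0
  out[ok] <- log((returns[ok] + continuity) /
                   (smolts[ok] - returns[ok] + continuity))
  out
}

#' Steelhead life-cycle series
#'
#' Aligned annual series for the Steelhead submodel, indexed by the cohort's
#' smolt out-migration year: smolt cohort abundance `F_t`, observed logit
#' marine survival, returning adult females `S_t`, and median upstream run
#' date `T_t` (day of year). `NA` marks missing observations.
#'
#' @param years Integer vector of years.
#' @param smolts,adults,run_date Numeric vectors (NA allowed).
#' @param logit_survival Observed logit survival; computed from
#'   `adults/smolts` via [logit_survival_obs()] when `NULL`.
#' @return An object of class `steelhead_series`.
#' @export
steelhead_series <- function(years, smolts, adults, run_date,
                             logit_survival = NULL) {
  years <- as.integer(years)
  n <- length(years)
  stopifnot(length(smolts) == n, length(adults) == n, length(run_date) == n)
  if (is.null(logit_survival))
    logit_survival <- logit_survival_obs(adults, smolts)
  structure(list(years = years, smolts = as.numeric(smolts),
                 adults = as.numeric(adults), run_date = as.numeric(run_date),
                 logit_survival = as.numeric(logit_survival)),
            class = "steelhead_series")
}

#' @export
print.steelhead_series <- function(x, ...) {
  cat(sprintf("<steelhead_series> %d-%d (%d years; missing: %d adults, %d smolts, %d run dates)\n",
              min(x$years), max(x$years), length(x$years),
              sum(is.na(x$adults)), sum(is.na(x$smolts)),
              sum(is.na(x$run_date))))
  invisible(x)
}

#' Climate window covariate from daily weather
#'
#' Aggregates a daily weather variable over a fixed window anchored on an
#' annual event date (e.g., mean air temperature over the 14 days before the
#' median upstream migration, or total rainfall over the 30 days after it).
#'
#' @param weather Data frame with columns `date` (Date) and the variable named
#'   by `var`.
#' @param years Integer vector of calendar years.
#' @param anchor_doy Numeric vector (recycled) of anchor day-of-year per year.
#' @param days Window length in days; negative values take the window before
#'   the anchor, positive after (anchor day excluded in both cases).
#' @param var Column of `weather` to aggregate.
#' @param fun Aggregation function (e.g., `mean` for temperature, `sum` for
#'   rainfall).
#' @return A [cov_series] over `years`.
#' @export
window_covariate <- function(weather, years, anchor_doy, days, var,
                             fun = mean) {
  stopifnot(all(c("date", var) %in% names(weather)))
  anchor_doy <- rep_len(anchor_doy, length(years))
  doy <- as.POSIXlt(weather$date)$yday + 1
  yr <- as.POSIXlt(weather$date)$year + 1900
  serial <- as.numeric(weather$date)
  vals <- vapply(seq_along(years), function(i) {
    a <- serial[which(yr == years[i] & doy == round(anchor_doy[i]))[1]]
    if (is.na(a)) stop("no daily weather at anchor day ", round(anchor_doy[i]),
                       " of year ", years[i])
    rng <- if (days < 0) c(a + days, a - 1) else c(a + 1, a + days)
    sel <- serial >= rng[1] & serial <= rng[2]
    if (!any(sel)) stop("daily weather does not cover the window in ", years[i])
    fun(weather[[var]][sel])
  }, numeric(1))
  cov_series(paste0(var, ifelse(days < 0, "_pre", "_post"), abs(days)),
             years, vals)
}

#' Log density of the Steelhead life-cycle block
#'
#' Sums the Gaussian observation log-densities of observed logit survival,
#' adult returns and run timing around their linear predictors, plus the
#' Gaussian random-walk process densities of the three intercept paths.
#' Dropping this block from the joint model leaves exactly the community
#' density ([close_life_cycle()] is their sum). Years with a missing adult
#' count contribute no returns term, and (because `ln S_t` is then undefined)
#' no timing term.
#'
#' @param state List with elements `m0` (length-T path), `S0`, `T0`,
#'   `delta_m`, `delta_S1`, `delta_S2`, `delta_TS`, `delta_T`,
#'   `sigma_m`, `sigma_S`, `sigma_T` (observation SDs), `sigma_um`,
#'   `sigma_uS`, `sigma_uT` (random-walk SDs), optional `init_sd` (default 10).
#' @param data A [steelhead_series].
#' @param design_m Standardized [design_matrix] of marine covariates.
#' @param design_t Standardized [design_matrix] of timing covariates.
#' @param include_init Include Gaussian initial-state densities. The first
#'   cohort's survival has no observed antecedent and is treated as missing
#'   data with a vague normal prior (the initial-state density).
#' @return Log density (scalar).
#' @export
steelhead_log_density <- function(state, data, design_m, design_t,
                                  include_init = TRUE) {
  T_ <- length(data$years)
  stopifnot(length(state$m0) == T_, length(state$S0) == T_,
            length(state$T0) == T_)
  Xm <- design_m$values[match(data$years, design_m$brood_years), , drop = FALSE]
  Xt <- design_t$values[match(data$years, design_t$brood_years), , drop = FALSE]
  if (anyNA(Xm) || anyNA(Xt)) stop("designs must cover all years, imputed")
  ld <- 0
  for (t in seq_len(T_)) {
    m_t <- marine_survival(state$m0[t], state$delta_m, Xm[t, ])
    if (!is.na(data$logit_survival[t]))
      ld <- ld + dnorm(data$logit_survival[t], m_t, state$sigma_m, log = TRUE)
    if (!is.na(data$adults[t])) {
      mu_S <- adult_returns(state$S0[t], state$delta_S1, m_t,
                            state$delta_S2,
                            if (is.na(data$smolts[t])) 0 else data$smolts[t])
      ld <- ld + dnorm(data$adults[t], mu_S, state$sigma_S, log = TRUE)
      if (!is.na(data$run_date[t]) && data$adults[t] > 0) {
        mu_T <- run_timing(state$T0[t], state$delta_TS, data$adults[t],
                           state$delta_T, Xt[t, ])
        ld <- ld + dnorm(data$run_date[t], mu_T, state$sigma_T, log = TRUE)
      }
    }
  }
  for (t in 2:T_) {
    ld <- ld + dnorm(state$m0[t], state$m0[t - 1], state$sigma_um, log = TRUE)
    ld <- ld + dnorm(state$S0[t], state$S0[t - 1], state$sigma_uS, log = TRUE)
    ld <- ld + dnorm(state$T0[t], state$T0[t - 1], state$sigma_uT, log = TRUE)
  }
  if (include_init) {
    s0 <- if (is.null(state$init_sd)) 10 else state$init_sd
    ld <- ld + dnorm(state$m0[1], 0, s0, log = TRUE) +
      dnorm(state$S0[1], 0, s0 * 100, log = TRUE) +
      dnorm(state$T0[1], mean(data$run_date, na.rm = TRUE), s0 * 10, log = TRUE)
  }
  ld
}

#' Joint log density of the integrated life-cycle model
#'
#' The community stock-recruitment density plus the Steelhead life-cycle block;
#' the two share the Steelhead brood-year alignment, and the joint density
#' factorizes so that removing the life-cycle block recovers the community
#' density exactly.
#'
#' @param community_state,broods,designs,variant As in
#'   [community_log_density()].
#' @param steelhead_state,steelhead_data,design_m,design_t As in
#'   [steelhead_log_density()]; pass `steelhead_state = NULL` to drop the
#'   life-cycle block.
#' @param include_init Include initial-state densities in both blocks.
#' @return Log density (scalar).
#' @export
close_life_cycle <- function(community_state, broods, designs,
                             steelhead_state = NULL, steelhead_data = NULL,
                             design_m = NULL, design_t = NULL,
                             variant = "alpha_varying", include_init = TRUE) {
  ld <- community_log_density(community_state, broods, designs,
                              variant = variant, include_init = include_init)
  if (!is.null(steelhead_state)) {
    ld <- ld + steelhead_log_density(steelhead_state, steelhead_data,
                                     design_m, design_t,
                                     include_init = include_init)
  }
  ld
}
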