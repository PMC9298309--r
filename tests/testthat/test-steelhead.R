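# Steelhead life-cycle components: survival, returns, timing, random walks,
# climate windows, and the joint life-cycle density.

test_that("logit marine survival and its inverse are exact", {
  expect_identical(marine_survival(0.7), 0.7)
  m <- marine_survival(0, -1, 2)
  expect_identical(m, -2)
  expect_lt(abs(plogis(m) - 0.11920292), 1e-8)
  expect_identical(marine_survival(1.3, 0, 99), 1.3)
  expect_error(marine_survival(NA), "non-finite")
  # inverse-logit is always a probability
  xs <- plogis(vapply(seq(-30, 30, by = 5), marine_survival, numeric(1)))
  expect_true(all(xs > 0 & xs < 1))
})

test_that("adult returns are a symmetric linear form", {
  expect_identical(adult_returns(10, 0, -2, 0, 1000), 10)
  expect_identical(adult_returns(10, 5, -2, 0.01, 1000), 10)
  # equal standardized effect sizes move returns equally
  d <- 0.7
  base <- adult_returns(100, d, 0, d, 0)
  expect_equal(adult_returns(100, d, 1, d, 0) - base,
               adult_returns(100, d, 0, d, 1) - base)
  expect_error(adult_returns(1, 1, 1, 1, -5), "non-negative")
})

test_that("run timing is log-linear in spawners", {
  expect_identical(run_timing(120), 120)
  expect_equal(run_timing(120, -5, exp(2), 3, 1), 113)
  t1 <- run_timing(120, -5, 300)
  t2 <- run_timing(120, -5, 600)
  expect_equal(t2 - t1, -5 * log(2), tolerance = 1e-12)
  expect_error(run_timing(120, -5, 0), "positive")
})

test_that("random walk paths cumulate innovations", {
  expect_identical(random_walk_path(0, c(1, -1)), c(0, 1, 0))
  expect_identical(random_walk_path(3), 3)
  expect_true(all(random_walk_path(2, rep(0, 10)) == 2))
})

test_that("random-walk variance grows linearly in time", {
  set.seed(30)
  T_ <- 50; n <- 20000
  paths <- matrix(rnorm(n * T_, sd = 0.5), n, T_)
  paths <- t(apply(paths, 1, cumsum))
  v <- apply(paths, 2, var)
  expect_lt(abs(v[T_] / v[T_ %/% 2] - 2), 0.1)
  fitl <- lm(v ~ seq_len(T_))
  expect_gt(summary(fitl)$r.squared, 0.99)
  expect_lt(abs(coef(fitl)[2] - 0.25) / 0.25, 0.05)
})

test_that("empirical logit survival applies the continuity correction", {
  expect_equal(logit_survival_obs(5, 100), log(5.5 / 95.5))
  expect_equal(logit_survival_obs(0, 100), log(0.5 / 100.5))
  expect_true(is.na(logit_survival_obs(NA, 100)))
})

test_that("window covariates aggregate daily weather around an anchor", {
  dates <- seq(as.Date("1999-12-01"), as.Date("2001-12-31"), by = "day")
  w <- data.frame(date = dates,
                  temp = seq_along(dates),
                  rain = rep(1, length(dates)))
  # 14 days before day-of-year 100 of 2000 (2000 is a leap year)
  a <- which(dates == as.Date("2000-04-09"))  # doy 100
  got <- window_covariate(w, 2000, 100, -14, "temp", mean)
  expect_equal(got$values, mean(w$temp[(a - 14):(a - 1)]))
  got2 <- window_covariate(w, 2000, 100, 30, "rain", sum)
  expect_equal(got2$values, 30)
  expect_error(window_covariate(w, 2005, 100, -14, "temp"), "2005")
})

test_that("life-cycle log density matches a hand-built oracle and factorizes", {
  T_ <- 3
  years <- 2000:2002
  sr <- steelhead_series(years, smolts = c(1000, 1200, 900),
                         adults = c(80, 60, 70),
                         run_date = c(120, 110, 115))
  Xm <- design_matrix("steelhead", years, cbind(oc = c(0.5, -0.5, 0)))
  Xt <- design_matrix("steelhead", years, cbind(tp = c(1, 0, -1)))
  st <- list(m0 = c(-2, -2.1, -2.2), S0 = c(50, 55, 60), T0 = c(130, 128, 126),
             delta_m = -0.5, delta_S1 = 10, delta_S2 = 0.02,
             delta_TS = -4, delta_T = 2,
             sigma_m = 0.3, sigma_S = 20, sigma_T = 5,
             sigma_um = 0.1, sigma_uS = 10, sigma_uT = 2)
  got <- steelhead_log_density(st, sr, Xm, Xt, include_init = FALSE)
  want <- 0
  for (t in 1:T_) {
    m <- st$m0[t] + st$delta_m * Xm$values[t, ]
    want <- want + dnorm(sr$logit_survival[t], m, st$sigma_m, log = TRUE)
    muS <- st$S0[t] + st$delta_S1 * m + st$delta_S2 * sr$smolts[t]
    want <- want + dnorm(sr$adults[t], muS, st$sigma_S, log = TRUE)
    muT <- st$T0[t] + st$delta_TS * log(sr$adults[t]) + st$delta_T * Xt$values[t, ]
    want <- want + dnorm(sr$run_date[t], muT, st$sigma_T, log = TRUE)
  }
  for (t in 2:T_) want <- want +
    dnorm(st$m0[t], st$m0[t - 1], st$sigma_um, log = TRUE) +
    dnorm(st$S0[t], st$S0[t - 1], st$sigma_uS, log = TRUE) +
    dnorm(st$T0[t], st$T0[t - 1], st$sigma_uT, log = TRUE)
  expect_equal(got, want, tolerance = 1e-10)

  # dropping the life-cycle block reduces the joint density to the community's
  dat <- sim_model_data(31, T_ = 3, d = 2)
  cstate <- list(ln_alpha = matrix(2, 3, 2), beta = c(0.001, 0.001),
                 delta = list(c(0, 0), c(0, 0)),
                 Sigma_O = diag(2) * 0.2, Sigma_P = diag(2) * 0.05)
  full <- close_life_cycle(cstate, dat$broods, dat$designs,
                           steelhead_state = st, steelhead_data = sr,
                           design_m = Xm, design_t = Xt,
                           include_init = FALSE)
  comm <- close_life_cycle(cstate, dat$broods, dat$designs,
                           include_init = FALSE)
  expect_equal(full - comm, got, tolerance = 1e-10)
})

test_that("years with missing adults contribute no returns or timing terms", {
  years <- 2000:2003
  sr <- steelhead_series(years, smolts = rep(1000, 4),
                         adults = c(80, NA, 70, 60),
                         run_date = c(120, 118, NA, 115))
  Xm <- design_matrix("steelhead", years, cbind(oc = rep(0, 4)))
  Xt <- design_matrix("steelhead", years, cbind(tp = rep(0, 4)))
  st <- list(m0 = rep(-2, 4), S0 = rep(60, 4), T0 = rep(125, 4),
             delta_m = 0, delta_S1 = 0, delta_S2 = 0, delta_TS = 0,
             delta_T = 0, sigma_m = 0.3, sigma_S = 20, sigma_T = 5,
             sigma_um = 0.1, sigma_uS = 10, sigma_uT = 2)
  ld <- steelhead_log_density(st, sr, Xm, Xt, include_init = FALSE)
  want <- sum(dnorm(sr$logit_survival[!is.na(sr$adults)], -2, 0.3, log = TRUE)) +
    sum(dnorm(c(80, 70, 60), 60, 20, log = TRUE)) +
    sum(dnorm(c(120, 115), 125, 5, log = TRUE)) +
    3 * (dnorm(0, 0, 0.1, log = TRUE) + dnorm(0, 0, 10, log = TRUE) +
           dnorm(0, 0, 2, log = TRUE))
  expect_equal(ld, want, tolerance = 1e-10)
})

test_that("a strong ocean effect on survival is recovered with high certainty", {
  cfg <- generator_config()
  cfg$steelhead_lc$delta_m <- c(ocean_interactions = -1, ocean_pca2 = -0.2)
  ds <- suppressWarnings(generate_dataset(cfg, seed = 301))
  fit <- fit_steelhead(ds$steelhead$series, ds$steelhead$design_m,
                       ds$steelhead$design_t, seed = 302, iter = 800)
  sp <- sign_probability(fit$draws$delta_m[, "ocean_interactions"])
  expect_gt(sp["negative"], 0.9)
})
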