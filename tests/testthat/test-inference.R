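# Sampler correctness (conjugate oracle, determinism), convergence
# diagnostics, sign probabilities, and PSIS-LOO.

test_that("posterior for a single-series level model matches grid quadrature", {
  # one species, spawners ~ 0 and no covariates: stationary model reduces to
  # y_t ~ N(a, s2) with a ~ N(0, 25) and s2 ~ IG(nu0/2, scale/2)
  set.seed(40)
  T_ <- 50
  y <- rnorm(T_, mean = 1.3, sd = 0.5)
  bt <- brood_table("one", seq_len(T_) + 1975, rep(1e-9, T_),
                    1e-9 * exp(y))
  dm <- design_matrix("one", seq_len(T_) + 1975,
                      matrix(numeric(0), T_, 0))
  fit <- fit_community(list(one = bt), list(one = dm),
                       variant = "stationary", chains = 2, iter = 4000,
                       seed = 41,
                       priors = community_priors(beta_sd = 1e-8))
  # independent oracle: 2-d grid quadrature over (a, s2)
  nu0 <- 2; sc <- 0.05   # the fit's defaults at d = 1
  agrid <- seq(0.8, 1.8, length.out = 400)
  s2grid <- seq(0.05, 0.6, length.out = 400)
  lp <- outer(agrid, s2grid, function(a, s2) {
    va <- vapply(seq_along(a), function(i)
      sum(dnorm(y, a[i], sqrt(s2[i]), log = TRUE)), numeric(1))
    va + dnorm(a, 0, 5, log = TRUE) +
      (-(nu0 / 2 + 1) * log(s2) - sc / (2 * s2))
  })
  w <- exp(lp - max(lp)); w <- w / sum(w)
  post_mean <- sum(outer(agrid, rep(1, length(s2grid))) * w)
  post_sd <- sqrt(sum(outer(agrid^2, rep(1, length(s2grid))) * w) - post_mean^2)
  a_draws <- fit$draws$ln_alpha[, "one"]
  mc_se <- post_sd / sqrt(200)  # conservative effective draw count
  expect_lt(abs(mean(a_draws) - post_mean), 4 * mc_se)
  expect_lt(abs(sd(a_draws) - post_sd) / post_sd, 0.15)
})

test_that("sampling is deterministic under a fixed seed", {
  dat <- sim_model_data(42, T_ = 15, d = 2)
  f1 <- fit_community(dat$broods, dat$designs, chains = 2, iter = 200,
                      seed = 99)
  f2 <- fit_community(dat$broods, dat$designs, chains = 2, iter = 200,
                      seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(summary_table(f1), summary_table(f2))
  f3 <- fit_community(dat$broods, dat$designs, chains = 2, iter = 200,
                      seed = 100)
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("the production profile retains 30,000 draws", {
  pf <- salmonregimes:::resolve_profile("production", 2, 10)
  expect_equal(pf$chains, 6L)
  expect_equal(pf$iter, 10000L)
  retained <- pf$chains * (pf$iter - floor(pf$iter * 0.5))
  expect_equal(retained, 30000L)
})

test_that("PSRF is near 1 for identical chains and large for shifted chains", {
  set.seed(43)
  x <- rnorm(4000)
  chain <- rep(1:2, each = 2000)
  expect_lt(psrf(x, chain), 1.05)
  shifted <- x + ifelse(chain == 2, 3, 0)
  expect_gt(psrf(shifted, chain), 1.1)
})

test_that("ESS collapses for strongly autocorrelated chains", {
  set.seed(44)
  n <- 4000
  ar <- as.numeric(arima.sim(list(ar = 0.99), n))
  chain <- rep(1:2, each = n / 2)
  expect_lt(ess(ar, chain), n / 10)
  iid <- rnorm(n)
  expect_gt(ess(iid, chain), n / 2)
})

test_that("convergence_report flags the constructed non-convergent fixture", {
  dat <- sim_model_data(45, T_ = 12, d = 2)
  fit <- fit_community(dat$broods, dat$designs, chains = 2, iter = 300,
                       seed = 46)
  rep_ok <- convergence_report(fit, ess_threshold = 10)
  expect_true(all(c("parameter", "psrf", "ess", "converged") %in%
                    names(rep_ok)))
  # corrupt one parameter's second chain: must be flagged
  fit$draws$beta[fit$chain == 2, 1] <- fit$draws$beta[fit$chain == 2, 1] + 5
  rep_bad <- convergence_report(fit, ess_threshold = 10, pars = "beta")
  expect_gt(rep_bad$psrf[rep_bad$parameter == "sp1"], 1.1)
  expect_false(rep_bad$converged[rep_bad$parameter == "sp1"])
  fit$chain <- rep(1L, length(fit$chain))
  expect_error(convergence_report(fit), "2 chains")
})

test_that("sign probabilities count posterior mass", {
  expect_equal(sign_probability(c(-1, 2, 3, 4))[["positive"]], 0.75)
  expect_equal(sign_probability(rep(2, 10))[["positive"]], 1)
  set.seed(47)
  s <- sign_probability(rnorm(20000))
  expect_lt(abs(s[["positive"]] - 0.5), 0.02)
  expect_error(sign_probability(numeric(0)), "no draws")
})

test_that("generalized Pareto tail fit recovers the shape parameter", {
  set.seed(48)
  k <- 0.3; sigma <- 1
  u <- runif(3000)
  x <- sigma * (u^(-k) - 1) / k   # inverse-cdf GPD draws
  g <- salmonregimes:::fit_gpd(x)
  expect_lt(abs(g$k - k), 0.1)
  expect_lt(abs(g$sigma - sigma) / sigma, 0.2)
})

test_that("PSIS-LOO agrees with exact leave-one-out on a conjugate model", {
  # y_i ~ N(mu, 1), mu ~ N(0, 10^2): both posterior and LOO predictive are
  # available in closed form
  set.seed(49)
  n <- 50; S <- 8000
  y <- rnorm(n, 0.7, 1)
  post_var <- 1 / (n + 1 / 100)
  mu_draws <- rnorm(S, post_var * sum(y), sqrt(post_var))
  ll <- vapply(seq_len(n), function(i) dnorm(y[i], mu_draws, 1, log = TRUE),
               numeric(S))
  loo <- loo_elpd(ll)
  exact <- vapply(seq_len(n), function(i) {
    vi <- 1 / (n - 1 + 1 / 100)
    mi <- vi * sum(y[-i])
    dnorm(y[i], mi, sqrt(1 + vi), log = TRUE)
  }, numeric(1))
  expect_lt(abs(loo$elpd - sum(exact)), loo$se)
  expect_lt(max(loo$pareto_k, na.rm = TRUE), 0.7)
})

test_that("LOO comparison ranks models and reports near-zero self-difference", {
  set.seed(50)
  n <- 60; S <- 4000
  y <- rnorm(n)
  post_var <- 1 / (n + 1 / 100)
  mu_draws <- rnorm(S, post_var * sum(y), sqrt(post_var))
  ll_true <- vapply(seq_len(n), function(i)
    dnorm(y[i], mu_draws, 1, log = TRUE), numeric(S))
  # overfit variant: one free mean per observation, fitted to the noise
  ll_over <- vapply(seq_len(n), function(i) {
    vi <- 1 / (1 + 1 / 4)   # one loosely constrained mean per observation
    mi <- vi * y[i]
    dnorm(y[i], rnorm(S, mi, sqrt(vi)), 1, log = TRUE)
  }, numeric(S))
  cmp <- compare_variants(list(true_model = ll_true, overfit = ll_over))
  expect_equal(cmp$model[1], "true_model")
  self <- compare_variants(list(a = ll_true, b = ll_true))
  expect_lt(abs(self$elpd_diff[2]), max(self$se_diff[2], 1e-8))
  expect_error(compare_variants(list(a = ll_true, b = ll_true[, 1:10])),
               "mismatched")
})
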