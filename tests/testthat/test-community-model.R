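# Ricker forms, the joint community log density, model variants, and
# observation simulation.

test_that("Ricker closed forms are exact", {
  expect_identical(ricker_recruits(5, 0.001, 0), 0)
  alpha <- 5; beta <- 0.001
  expect_lt(abs(ricker_recruits(alpha, beta, 1 / beta) - alpha / (beta * exp(1))),
            1e-10)
  expect_lt(abs(ricker_recruits(5, 0.001, 1000) - 5000 * exp(-1)), 1e-10)
  # the maximum really is at S = 1/beta
  S <- seq(1, 5000, by = 1)
  R <- ricker_recruits(alpha, beta, S)
  expect_equal(S[which.max(R)], 1 / beta)
  expect_error(ricker_recruits(-1, 0.001, 10), "alpha")
  expect_error(ricker_recruits(1, 0.001, -10), "non-negative")
})

test_that("linearized Ricker predictor is exact arithmetic", {
  expect_identical(ricker_expected_log_rps(1, 0.002, 500, 0.3, -1), -0.3)
  expect_identical(ricker_expected_log_rps(2.5, 0, 1000), 2.5)
  expect_identical(ricker_expected_log_rps(1.7, 0.002, 0), 1.7)
  expect_error(ricker_expected_log_rps(Inf, 1, 1), "non-finite")
  expect_error(ricker_expected_log_rps(1, 1, 1, c(1, 2), 1), "conformable")
})

test_that("community log density matches a scalar oracle on a diagonal fixture", {
  T_ <- 2; d <- 2
  years <- 1976:1977
  S <- matrix(c(100, 200, 300, 400), T_, d)
  A <- matrix(c(1, 1.2, 0.8, 0.7), T_, d)
  beta <- c(0.001, 0.002)
  X <- list(cbind(x = c(0.5, -0.5)), cbind(x = c(1, -1)))
  delta <- list(0.3, -0.2)
  sO <- c(0.4, 0.5); sP <- c(0.2, 0.3)
  broods <- lapply(1:d, function(j)
    brood_table(paste0("sp", j), years, S[, j],
                S[, j] * exp(c(0.5, -0.1) + 0.1 * j)))
  names(broods) <- paste0("sp", 1:d)
  designs <- lapply(1:d, function(j)
    design_matrix(paste0("sp", j), years, X[[j]]))
  state <- list(ln_alpha = A, beta = beta, delta = delta,
                Sigma_O = diag(sO^2), Sigma_P = diag(sP^2), ln_alpha0_sd = 5)
  got <- community_log_density(state, broods, designs)
  Y <- sapply(broods, function(b) b$log_rps)
  want <- 0
  for (t in 1:T_) for (j in 1:d) {
    mu <- A[t, j] - beta[j] * S[t, j] + delta[[j]] * X[[j]][t, ]
    want <- want + dnorm(Y[t, j], mu, sO[j], log = TRUE)
  }
  for (j in 1:d) want <- want + dnorm(A[2, j], A[1, j], sP[j], log = TRUE) +
    dnorm(A[1, j], 0, 5, log = TRUE)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("stationary density is the alpha-varying density at zero innovations", {
  dat <- sim_model_data(20, T_ = 8, d = 2)
  a0 <- c(1.5, 2.0)
  T_ <- 8
  state_tv <- list(ln_alpha = matrix(rep(a0, each = T_), T_, 2),
                   beta = c(0.001, 0.002),
                   delta = list(c(0.2, -0.1), c(0, 0.3)),
                   Sigma_O = diag(c(0.16, 0.25)),
                   Sigma_P = diag(2))
  state_st <- state_tv; state_st$ln_alpha <- a0
  ld_tv <- community_log_density(state_tv, dat$broods, dat$designs,
                                 "alpha_varying", include_init = FALSE)
  ld_st <- community_log_density(state_st, dat$broods, dat$designs,
                                 "stationary")
  # the only difference is the process density of a constant path
  # (Sigma_P = diag(2) is the 2x2 identity)
  walk <- 2 * (T_ - 1) * dnorm(0, 0, 1, log = TRUE)
  expect_equal(ld_tv - walk, ld_st, tolerance = 1e-10)
})

test_that("community density is invariant to species relabeling", {
  dat <- sim_model_data(21, T_ = 10, d = 3)
  T_ <- 10
  state <- list(ln_alpha = matrix(rnorm(T_ * 3, 2), T_, 3),
                beta = c(0.001, 0.002, 0.003),
                delta = list(c(.1, .2), c(-.1, 0), c(.3, -.2)),
                Sigma_O = 0.2 * (diag(3) * 0.5 + 0.5),
                Sigma_P = 0.1 * (diag(3) * 0.7 + 0.3))
  ld <- community_log_density(state, dat$broods, dat$designs)
  perm <- c(3, 1, 2)
  state_p <- list(ln_alpha = state$ln_alpha[, perm],
                  beta = state$beta[perm], delta = state$delta[perm],
                  Sigma_O = state$Sigma_O[perm, perm],
                  Sigma_P = state$Sigma_P[perm, perm])
  ld_p <- community_log_density(state_p, dat$broods[perm], dat$designs[perm])
  expect_equal(ld, ld_p, tolerance = 1e-10)
})

test_that("model variants are built and counted correctly", {
  v <- build_variant("alpha_varying")
  expect_true(v$alpha_tv); expect_false(v$beta_tv)
  expect_error(build_variant("quadratic"), "arg")
  T_ <- 40; d <- 5; K <- 15
  n_a <- n_parameters("alpha_varying", T_, d, K)
  n_b <- n_parameters("both", T_, d, K)
  n_s <- n_parameters("stationary", T_, d, K)
  # 'both' replaces d constant betas by d*T states and adds a process block
  expect_equal(n_b - n_a, d * (T_ - 1) + d * (d + 1) / 2)
  expect_equal(n_a - n_s, d * (T_ - 1) + d * (d + 1) / 2)
})

test_that("observation simulation is exact in its degenerate limits", {
  st <- list(ln_alpha = c(1, 2), beta = c(0.001, 0.002),
             delta = list(0.5, -0.5), Sigma_O = matrix(0, 2, 2))
  mu <- c(ricker_expected_log_rps(1, 0.001, 100, 0.5, 1),
          ricker_expected_log_rps(2, 0.002, 200, -0.5, 1))
  got <- simulate_observation(st, c(100, 200), list(1, 1), n = 3)
  expect_true(all(abs(sweep(got, 2, mu)) < 1e-12))
  # location equivariance
  st2 <- st; st2$Sigma_O <- diag(2) * 0.25
  set.seed(5); d1 <- simulate_observation(st2, c(100, 200), list(1, 1), n = 50)
  st3 <- st2; st3$ln_alpha <- st2$ln_alpha + 1
  set.seed(5); d2 <- simulate_observation(st3, c(100, 200), list(1, 1), n = 50)
  expect_equal(d2, d1 + 1, tolerance = 1e-12)
  bad <- st; bad$Sigma_O <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simulate_observation(bad, c(1, 1), list(0, 0)),
               "positive definite")
})

test_that("simulated observation noise matches the requested covariance", {
  st <- list(ln_alpha = c(0, 0), beta = c(0, 0), delta = list(numeric(0),
             numeric(0)), Sigma_O = diag(2))
  set.seed(6)
  draws <- simulate_observation(st, c(0, 0), list(numeric(0), numeric(0)),
                                n = 1e5)
  expect_lt(max(abs(cov(draws) - diag(2))), 0.03)
})
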