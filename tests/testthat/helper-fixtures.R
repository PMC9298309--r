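# Shared fixtures: small model-correct datasets and fake fit objects for
# summary-level tests that do not need MCMC.

# simulate data exactly from the fitted model form (exogenous spawners,
# correlated random-walk intercepts, correlated observation noise); returns
# brood tables, standardized designs and the truth
sim_model_data <- function(seed, T_ = 40, d = 3, k = 2,
                           sigma_proc = 0.3, sigma_obs = 0.4,
                           proc_cor = 0.4, obs_cor = 0.2,
                           ln_alpha0 = NULL, beta = NULL, delta = NULL) {
  set.seed(seed)
  species <- paste0("sp", seq_len(d))
  years <- seq(1976, length.out = T_)
  if (is.null(ln_alpha0)) ln_alpha0 <- rep(2, d)
  if (is.null(beta)) beta <- rep(0.002, d)
  if (is.null(delta)) delta <- matrix(rnorm(d * k, 0, 0.5), d, k)
  SigP <- (diag(1 - proc_cor, d) + proc_cor) * sigma_proc^2
  SigO <- (diag(1 - obs_cor, d) + obs_cor) * sigma_obs^2
  A <- matrix(0, T_, d)
  A[1, ] <- ln_alpha0
  LP <- t(chol(SigP)); LO <- t(chol(SigO))
  for (t in 2:T_) A[t, ] <- A[t - 1, ] + drop(LP %*% rnorm(d))
  S <- matrix(exp(rnorm(T_ * d, log(500), 0.5)), T_, d)
  X <- lapply(seq_len(d), function(j) {
    m <- matrix(rnorm(T_ * k), T_, k,
                dimnames = list(NULL, paste0("x", seq_len(k))))
    scale(m) * sqrt(T_ / (T_ - 1))   # population-SD standardization
  })
  MU <- sapply(seq_len(d), function(j)
    A[, j] - beta[j] * S[, j] + drop(X[[j]] %*% delta[j, ]))
  Y <- MU + t(LO %*% matrix(rnorm(T_ * d), d, T_))
  broods <- lapply(seq_len(d), function(j)
    brood_table(species[j], years, S[, j], S[, j] * exp(Y[, j])))
  names(broods) <- species
  designs <- lapply(seq_len(d), function(j)
    standardize(design_matrix(species[j], years, X[[j]])))
  names(designs) <- species
  list(broods = broods, designs = designs, years = years, species = species,
       truth = list(ln_alpha = A, beta = beta, delta = delta,
                    Sigma_P = SigP, Sigma_O = SigO, mu = MU, Y = Y, S = S))
}

# minimal community_fit-shaped object for summary functions
fake_community_fit <- function(ln_alpha_draws, years, species,
                               delta = NULL, designs = NULL) {
  structure(list(
    variant = build_variant("alpha_varying"),
    species = species, years = years,
    draws = list(ln_alpha = ln_alpha_draws, delta = delta),
    data = list(designs = designs)
  ), class = "community_fit")
}

# brute-force log density of a multivariate normal, independent of package code
mvn_ld_ref <- function(x, mu, S) {
  -0.5 * (length(x) * log(2 * pi) + determinant(S)$modulus[1] +
            drop(t(x - mu) %*% solve(S) %*% (x - mu)))
}
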