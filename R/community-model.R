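# Joint probability model for multi-species recruitment productivity:
# a linearized Ricker observation equation with a time-varying intercept
# (intrinsic productivity as a correlated multivariate random walk) and full
# observation/process covariance matrices.

#' Brood-year stock-recruitment table for one species
#'
#' @param species Single string.
#' @param brood_years Integer vector.
#' @param spawners Non-negative spawner abundances per brood year (`NA` where
#'   unobserved). Adult females for species counted as such; post-spawn
#'   downstream counts where those proxy total spawners.
#' @param recruits Non-negative recruit abundances (`NA` where unobserved):
#'   smolt out-migrants, or returning adults two years after the brood year
#'   for species without a freshwater rearing stage.
#' @param recruit_definition `"smolt_outmigrants"` or `"adults_t_plus_2"`.
#'
#' @return An object of class `brood_table` with a derived `log_rps` column,
#'   the observed recruitment productivity ln(R/S) (NA where either side is
#'   missing or non-positive).
#' @export
brood_table <- function(species, brood_years, spawners, recruits,
                        recruit_definition = c("smolt_outmigrants",
                                               "adults_t_plus_2")) {
  recruit_definition <- match.arg(recruit_definition)
  brood_years <- as.integer(brood_years)
  if (length(spawners) != length(brood_years) ||
      length(recruits) != length(brood_years))
    stop("spawners and recruits must have one value per brood year")
  if (any(spawners < 0, na.rm = TRUE) || any(recruits < 0, na.rm = TRUE))
    stop("spawners and recruits must be non-negative")
  ok <- !is.na(spawners) & !is.na(recruits) & spawners > 0 & recruits > 0
  log_rps <- ifelse(ok, log(recruits / spawners), NA_real_)
  structure(list(species = species, brood_years = brood_years,
                 spawners = as.numeric(spawners),
                 recruits = as.numeric(recruits),
                 log_rps = log_rps, missing = !ok,
                 recruit_definition = recruit_definition),
            class = "brood_table")
}

#' @export
print.brood_table <- function(x, ...) {
  cat(sprintf("<brood_table> %s: %d-%d, %d brood years (%d missing), recruits = %s\n",
              x$species, min(x$brood_years), max(x$brood_years),
              length(x$brood_years), sum(x$missing), x$recruit_definition))
  invisible(x)
}

#' Ricker stock-recruitment curve
#'
#' Expected recruits `R = alpha * S * exp(-beta * S)`. `alpha` is recruits per
#' spawner at vanishing density (maximum intrinsic productivity) and `1/beta`
#' is the spawner abundance that maximizes recruitment, at which
#' `R = alpha / (beta * e)`.
#'
#' @param alpha Intrinsic productivity (> 0).
#' @param beta Density-dependence coefficient.
#' @param S Spawner abundance (>= 0); vectorized.
#' @return Expected recruits.
#' @examples
#' ricker_recruits(5, 0.001, 1000) # 5000 * exp(-1)
#' @export
ricker_recruits <- function(alpha, beta, S) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (any(!is.finite(S)) || any(S < 0)) stop("S must be non-negative")
  alpha * S * exp(-beta * S)
}

#' Expected log recruitment productivity under the linearized Ricker model
#'
#' `E[ln(R/S)] = ln_alpha - beta * S + delta . x`, the regression form in which
#' intrinsic productivity, density dependence and standardized environmental
#' covariates act additively on log recruits-per-spawner.
#'
#' @param ln_alpha Log intrinsic productivity.
#' @param beta Density-dependence coefficient (>= 0 in fitted models).
#' @param S Spawner abundance (>= 0).
#' @param delta Covariate coefficient vector (may be empty).
#' @param x Covariate values, conformable with `delta`.
#' @return Expected ln(R/S).
#' @examples
#' ricker_expected_log_rps(1, 0.002, 500, 0.3, -1) # -0.3
#' @export
ricker_expected_log_rps <- function(ln_alpha, beta, S, delta = numeric(0),
                                    x = numeric(0)) {
  if (!all(is.finite(c(ln_alpha, beta, S, delta, x)))) stop("non-finite inputs")
  if (any(S < 0)) stop("S must be non-negative")
  if (length(delta) != length(x)) stop("delta and x must be conformable")
  ln_alpha - beta * S + sum(delta * x)
}

# log density of a multivariate normal (lower chol or covariance supplied)
dmvnorm_log <- function(x, mean, Sigma) {
  cS <- tryCatch(chol(Sigma), error = function(e)
    stop("covariance matrix is not positive definite"))
  z <- backsolve(cS, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(cS))) + sum(z^2))
}

#' Model variant specification
#'
#' The community model is fitted in nested variants that differ in which
#' stock-recruitment parameters follow a random walk: `alpha_varying` (the
#' selected structure: time-varying intrinsic productivity, constant density
#' dependence), `beta_varying`, `both`, or the fully `stationary` regression.
#'
#' @param variant One of `"alpha_varying"`, `"beta_varying"`, `"both"`,
#'   `"stationary"`.
#' @return A list of class `model_variant` with logical flags `alpha_tv`,
#'   `beta_tv`.
#' @export
build_variant <- function(variant = c("alpha_varying", "beta_varying", "both",
                                      "stationary")) {
  variant <- match.arg(variant)
  structure(list(
    name = variant,
    alpha_tv = variant %in% c("alpha_varying", "both"),
    beta_tv = variant %in% c("beta_varying", "both")
  ), class = "model_variant")
}

#' Free-parameter count of a model variant
#'
#' Counts states and parameters: each time-varying component contributes `T`
#' states per species (in place of 1 constant), plus per-species covariate
#' coefficients and the two covariance matrices.
#'
#' @param variant A `model_variant` or its name.
#' @param T_ Number of years.
#' @param n_species Number of species.
#' @param n_delta Total number of covariate coefficients across species.
#' @return Integer parameter count.
#' @export
n_parameters <- function(variant, T_, n_species, n_delta = 0) {
  if (is.character(variant)) variant <- build_variant(variant)
  covp <- n_species * (n_species + 1) / 2              # Sigma_O
  n_states <- 0L
  if (variant$alpha_tv) n_states <- n_states + 1L
  if (variant$beta_tv) n_states <- n_states + 1L
  covp <- covp + n_states * n_species * (n_species + 1) / 2  # Sigma_P blocks
  per_sr <- n_species * ((if (variant$alpha_tv) T_ else 1) +
                         (if (variant$beta_tv) T_ else 1))
  as.integer(per_sr + n_delta + covp)
}

# align a list of brood tables and design matrices on the union of brood years;
# returns Y (T x d), S (T x d), X (list of T x k matrices), years, species
align_community_data <- function(broods, designs) {
  stopifnot(length(broods) == length(designs))
  d <- length(broods)
  years <- sort(unique(unlist(lapply(broods, `[[`, "brood_years"))))
  T_ <- length(years)
  species <- vapply(broods, `[[`, character(1), "species")
  Y <- S <- matrix(NA_real_, T_, d, dimnames = list(years, species))
  X <- vector("list", d)
  for (j in seq_len(d)) {
    bt <- broods[[j]]; dm <- designs[[j]]
    if (!identical(bt$species, dm$species))
      stop("brood table and design matrix species mismatch: ",
           bt$species, " vs ", dm$species)
    if (!all(years %in% dm$brood_years))
      stop("design matrix for ", dm$species,
           " does not cover all aligned brood years")
    i <- match(bt$brood_years, years)
    Y[i, j] <- ifelse(bt$missing, NA_real_, bt$log_rps)
    S[i, j] <- bt$spawners
    X[[j]] <- dm$values[match(years, dm$brood_years), , drop = FALSE]
    if (anyNA(X[[j]])) stop("design matrix for ", dm$species,
                            " has missing entries; impute first")
  }
  list(Y = Y, S = S, X = X, years = years, species = species)
}

#' Joint log density of the community state-space model
#'
#' Sums (a) the multivariate normal observation log-density of the species
#' vector of observed ln(R/S) around its Ricker means with covariance
#' `Sigma_O`, (b) the multivariate random-walk process log-density of the
#' latent `ln alpha_t` path with covariance `Sigma_P` (for time-varying
#' variants), and optionally (c) log priors. Species-years with missing
#' observations contribute only through the process state (the observation
#' density is evaluated on the observed subvector).
#'
#' This reference implementation is independent of the compiled Gibbs sampler
#' and is used for nesting and permutation checks.
#'
#' @param state A list with elements `ln_alpha` (T x d matrix for time-varying
#'   variants, or length-d vector for stationary), `beta` (length d, > 0),
#'   `delta` (list of d coefficient vectors), `Sigma_O` (d x d),
#'   `Sigma_P` (d x d; ignored for stationary), and optionally `ln_alpha0_sd`
#'   (initial-state SD, default 5).
#' @param broods List of d [brood_table] objects.
#' @param designs List of d standardized [design_matrix] objects.
#' @param variant A `model_variant` or name (default `"alpha_varying"`).
#' @param include_init Include the Gaussian initial-state density of
#'   `ln alpha_1` (default `TRUE`).
#'
#' @return The log density (numeric scalar).
#' @export
community_log_density <- function(state, broods, designs,
                                  variant = "alpha_varying",
                                  include_init = TRUE) {
  if (is.character(variant)) variant <- build_variant(variant)
  if (variant$beta_tv)
    stop("reference density implemented for alpha_varying and stationary variants")
  ad <- align_community_data(broods, designs)
  T_ <- nrow(ad$Y); d <- ncol(ad$Y)
  A <- if (variant$alpha_tv) {
    if (!is.matrix(state$ln_alpha) || nrow(state$ln_alpha) != T_ ||
        ncol(state$ln_alpha) != d)
      stop("ln_alpha must be a ", T_, " x ", d, " matrix")
    state$ln_alpha
  } else matrix(rep(state$ln_alpha, each = T_), T_, d)
  beta <- state$beta
  if (any(beta < 0)) stop("beta must be non-negative")
  ld <- 0
  for (t in seq_len(T_)) {
    mu <- vapply(seq_len(d), function(j)
      ricker_expected_log_rps(A[t, j], beta[j], ad$S[t, j],
                              state$delta[[j]], ad$X[[j]][t, ]),
      numeric(1))
    o <- which(!is.na(ad$Y[t, ]))
    if (length(o) > 0L)
      ld <- ld + dmvnorm_log(ad$Y[t, o], mu[o],
                             state$Sigma_O[o, o, drop = FALSE])
  }
  if (variant$alpha_tv) {
    for (t in 2:T_)
      ld <- ld + dmvnorm_log(A[t, ], A[t - 1L, ], state$Sigma_P)
    if (include_init) {
      s0 <- if (is.null(state$ln_alpha0_sd)) 5 else state$ln_alpha0_sd
      ld <- ld + dmvnorm_log(A[1, ], rep(0, d), diag(s0^2, d))
    }
  }
  ld
}

#' Simulate one observation vector from the community model
#'
#' Draws the species vector of ln(R/S) at one time point from its multivariate
#' normal observation distribution, as used by posterior predictive checks.
#'
#' @param state List with `ln_alpha` (length-d vector for this time point),
#'   `beta`, `delta` (list), `Sigma_O`.
#' @param S_t Length-d spawner vector.
#' @param x_t List of d covariate vectors.
#' @param n Number of draws.
#' @return An `n x d` matrix of draws (deterministic under a fixed RNG seed;
#'   equal to the mean when `Sigma_O` is the zero matrix).
#' @export
simulate_observation <- function(state, S_t, x_t, n = 1) {
  d <- length(state$ln_alpha)
  mu <- vapply(seq_len(d), function(j)
    ricker_expected_log_rps(state$ln_alpha[j], state$beta[j], S_t[j],
                            state$delta[[j]], x_t[[j]]), numeric(1))
  Sig <- state$Sigma_O
  if (all(Sig == 0)) return(matrix(mu, n, d, byrow = TRUE))
  cS <- tryCatch(chol(Sig), error = function(e)
    stop("observation covariance is not positive definite"))
  Z <- matrix(rnorm(n * d), n, d)
  sweep(Z %*% cS, 2, mu, "+")
}
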