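# Posterior sampling wrappers around the compiled Gibbs cores, and the
# FitResult containers they return.

#' Prior settings for the community model
#'
#' Weakly informative conjugate priors: Normal(0, `delta_sd`^2) coefficients on
#' standardized covariates, half-Normal(0, `beta_sd`^2) density dependence on
#' the scaled-spawner axis (spawners are divided by their per-species maximum
#' inside the sampler), Normal(0, `a0_sd`^2) initial intrinsic productivity,
#' and inverse-Wishart(`nu0` = d + 1, `scale` * I) covariance matrices, whose
#' conjugacy the Gibbs sampler exploits.
#'
#' @param a0_sd SD of the initial `ln alpha` state prior.
#' @param beta_sd Half-normal SD for scaled density dependence.
#' @param delta_sd SD for covariate coefficients.
#' @param nu0 Inverse-Wishart degrees of freedom (`NULL` = d + 1, the smallest
#'   proper choice; with a small scale matrix the posterior mean of each
#'   variance then approximately equals its maximum-likelihood estimate, so
#'   the prior imposes almost no shrinkage).
#' @param SO_scale,SP_scale Diagonal of the inverse-Wishart scale matrices for
#'   the observation and process covariances.
#' @param sweeps Coordinate-Gibbs sweeps over the regression block per
#'   iteration.
#' @return A list of prior settings.
#' @export
community_priors <- function(a0_sd = 5, beta_sd = 5, delta_sd = 5, nu0 = NULL,
                             SO_scale = 0.05, SP_scale = 0.05, sweeps = 2L) {
  list(a0_sd = a0_sd, beta_sd = beta_sd, delta_sd = delta_sd, nu0 = nu0,
       SO_scale = SO_scale, SP_scale = SP_scale, sweeps = as.integer(sweeps))
}

resolve_profile <- function(profile, chains, iter) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("desk", "production"))
    if (profile == "desk") { chains <- 2L; iter <- 1500L }
    else { chains <- 6L; iter <- 10000L }
  }
  list(chains = as.integer(chains), iter = as.integer(iter))
}

#' Fit the community stock-recruitment model by MCMC
#'
#' Samples the joint posterior of the multivariate time-varying Ricker model by
#' a conjugate Gibbs sampler: latent intercept paths by forward-filter
#' backward-sampling, regression coefficients (initialized at zero) from their
#' Gaussian or truncated-Gaussian full conditionals, covariance matrices from
#' inverse-Wishart conditionals, and missing recruitment observations by exact
#' data augmentation. Runs are reproducible under `seed`.
#'
#' @param broods List of [brood_table] objects, one per species.
#' @param designs List of standardized [design_matrix] objects, aligned with
#'   `broods`.
#' @param variant Model variant name or [build_variant()] object.
#' @param chains,iter Number of chains and total iterations per chain.
#' @param warmup_frac Fraction of iterations discarded as warmup (default 0.5).
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer RNG seed (optional but recommended).
#' @param priors See [community_priors()].
#' @param profile `"desk"` (2 chains x 1,500 iterations, the default testing
#'   scale) or `"production"` (6 chains x 10,000, 50\% warmup, 30,000 retained
#'   draws); overrides `chains`/`iter` when given.
#'
#' @return An object of class `community_fit` with posterior `draws`
#'   (`ln_alpha` paths, raw-scale `beta`, named `delta`, `Sigma_O`, `Sigma_P`),
#'   a per-draw, per-year observation log-likelihood matrix `loglik`, the
#'   chain index of every draw, and the aligned data.
#' @export
fit_community <- function(broods, designs, variant = "alpha_varying",
                          chains = 2, iter = 1500, warmup_frac = 0.5,
                          thin = 1, seed = NULL,
                          priors = community_priors(), profile = NULL) {
  if (is.character(variant)) variant <- build_variant(variant)
  pf <- resolve_profile(profile, chains, iter)
  chains <- pf$chains; iter <- pf$iter
  if (chains < 1L || iter < 4L) stop("need at least 1 chain and 4 iterations")
  ad <- align_community_data(broods, designs)
  T_ <- nrow(ad$Y); d <- ncol(ad$Y)
  OBS <- !is.na(ad$Y)
  if (any(colSums(OBS) < 3L))
    stop("a species has fewer than 3 observed brood years")
  s_scale <- apply(ad$S, 2, max, na.rm = TRUE)
  Ss <- sweep(ad$S, 2, s_scale, "/")
  Ss[is.na(Ss)] <- 0
  Y0 <- ad$Y; Y0[!OBS] <- 0
  for (j in seq_len(d)) {
    dmj <- designs[[j]]
    if (ncol(dmj$values) > 0L && is.null(dmj$standardization))
      warning("design matrix for ", dmj$species,
              " is not standardized; effect sizes will not be comparable")
  }
  prior <- priors
  if (is.null(prior$nu0)) prior$nu0 <- d + 1
  n_warmup <- as.integer(floor(iter * warmup_frac))

  if (!is.null(seed)) set.seed(seed)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- gibbs_community_cpp(Y0, OBS * 1L, Ss, lapply(ad$X, as.matrix),
                                     variant$alpha_tv, variant$beta_tv,
                                     iter, n_warmup, as.integer(thin), prior)
  }
  n_keep <- nrow(res[[1]]$theta)
  chain_id <- rep(seq_len(chains), each = n_keep)
  theta <- do.call(rbind, lapply(res, `[[`, "theta"))
  loglik <- do.call(rbind, lapply(res, `[[`, "loglik"))
  colnames(loglik) <- ad$years

  K <- vapply(ad$X, ncol, integer(1))
  delta_names <- unlist(lapply(seq_len(d), function(j)
    if (K[j] > 0) paste0(ad$species[j], ":", colnames(ad$X[[j]])) else character(0)))
  na_ <- if (variant$alpha_tv) 0L else d
  nb_ <- if (variant$beta_tv) 0L else d
  draws <- list()
  if (!variant$alpha_tv) {
    draws$ln_alpha <- theta[, seq_len(d), drop = FALSE]
    colnames(draws$ln_alpha) <- ad$species
  }
  if (!variant$beta_tv) {
    bsc <- theta[, na_ + seq_len(d), drop = FALSE]
    draws$beta <- sweep(bsc, 2, s_scale, "/")
    colnames(draws$beta) <- ad$species
  }
  if (sum(K) > 0) {
    draws$delta <- theta[, na_ + nb_ + seq_len(sum(K)), drop = FALSE]
    colnames(draws$delta) <- delta_names
  } else draws$delta <- matrix(0, nrow(theta), 0)
  ds <- (variant$alpha_tv + variant$beta_tv) * d
  if (ds > 0) {
    st <- lapply(res, `[[`, "states")        # cubes [keep, T, ds]
    states <- array(0, c(n_keep * chains, T_, ds))
    for (ch in seq_len(chains))
      states[(ch - 1) * n_keep + seq_len(n_keep), , ] <- st[[ch]]
    offset <- 0L
    if (variant$alpha_tv) {
      draws$ln_alpha <- states[, , seq_len(d), drop = FALSE]
      dimnames(draws$ln_alpha) <- list(NULL, ad$years, ad$species)
      offset <- d
    }
    if (variant$beta_tv) {
      bt <- states[, , offset + seq_len(d), drop = FALSE]
      for (j in seq_len(d)) bt[, , j] <- bt[, , j] / s_scale[j]
      draws$beta_t <- bt
      dimnames(draws$beta_t) <- list(NULL, ad$years, ad$species)
    }
    SP <- lapply(res, `[[`, "Sigma_P")
    draws$Sigma_P <- array(0, c(n_keep * chains, ds, ds))
    for (ch in seq_len(chains))
      for (k in seq_len(n_keep))
        draws$Sigma_P[(ch - 1) * n_keep + k, , ] <- SP[[ch]][, , k]
  }
  SO <- lapply(res, `[[`, "Sigma_O")
  draws$Sigma_O <- array(0, c(n_keep * chains, d, d))
  for (ch in seq_len(chains))
    for (k in seq_len(n_keep))
      draws$Sigma_O[(ch - 1) * n_keep + k, , ] <- SO[[ch]][, , k]

  structure(list(
    variant = variant, species = ad$species, years = ad$years,
    draws = draws, loglik = loglik, chain = chain_id,
    chains = chains, iter = iter, warmup = n_warmup, thin = thin,
    seed = seed, priors = prior,
    data = list(Y = ad$Y, S = ad$S, Ss = Ss, s_scale = s_scale, X = ad$X,
                OBS = OBS, designs = designs, broods = broods)
  ), class = "community_fit")
}

#' @export
print.community_fit <- function(x, ...) {
  cat(sprintf("<community_fit> %s | %d species x %d years | %d chains x %d iter (%d retained draws)\n",
              x$variant$name, length(x$species), length(x$years),
              x$chains, x$iter, length(x$chain)))
  if (!is.null(x$draws$beta)) {
    bm <- colMeans(x$draws$beta)
    cat("posterior mean beta: ",
        paste(sprintf("%s=%.3g", x$species, bm), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten a fit into a draws matrix for diagnostics
#'
#' @param fit A `community_fit` or `steelhead_fit`.
#' @param pars Parameter groups to include.
#' @return A numeric matrix (draws x parameters) with named columns; the chain
#'   index of each row is in `attr(, "chain")`.
#' @export
param_matrix <- function(fit, pars = c("beta", "delta", "sigma", "ln_alpha")) {
  UseMethod("param_matrix")
}

#' @export
param_matrix.community_fit <- function(fit,
                                       pars = c("beta", "delta", "sigma",
                                                "ln_alpha")) {
  d <- length(fit$species); out <- list()
  if ("beta" %in% pars && !is.null(fit$draws$beta)) out$beta <- fit$draws$beta
  if ("delta" %in% pars && ncol(fit$draws$delta) > 0) out$delta <- fit$draws$delta
  if ("sigma" %in% pars) {
    so <- vapply(seq_len(d), function(j) sqrt(fit$draws$Sigma_O[, j, j]),
                 numeric(nrow(fit$loglik)))
    colnames(so) <- paste0("sigma_O[", fit$species, "]")
    out$sigma_O <- so
    if (!is.null(fit$draws$Sigma_P)) {
      ds <- dim(fit$draws$Sigma_P)[2]
      sp <- vapply(seq_len(ds), function(j) sqrt(fit$draws$Sigma_P[, j, j]),
                   numeric(nrow(fit$loglik)))
      colnames(sp) <- paste0("sigma_P[", seq_len(ds), "]")
      out$sigma_P <- sp
    }
  }
  if ("ln_alpha" %in% pars) {
    la <- fit$draws$ln_alpha
    if (length(dim(la)) == 3) {
      T_ <- dim(la)[2]
      m <- matrix(la, nrow = dim(la)[1])
      colnames(m) <- paste0("ln_alpha[", rep(fit$species, each = T_), ",",
                            rep(fit$years, times = length(fit$species)), "]")
      out$ln_alpha <- m
    } else {
      m <- la; colnames(m) <- paste0("ln_alpha[", fit$species, "]")
      out$ln_alpha <- m
    }
  }
  m <- do.call(cbind, out)
  attr(m, "chain") <- fit$chain
  m
}

#' Prior settings for the Steelhead life-cycle model
#'
#' @param delta_sd Normal prior SD for all regression coefficients (on the
#'   internally scaled data).
#' @param init_sd SDs of the vague normal initial-state priors for the
#'   survival, returns, and timing intercept paths (the first cohort's
#'   survival has no antecedent and is imputed from this prior).
#' @param a_obs,b_obs,a_rw,b_rw Inverse-gamma shape/scale for observation and
#'   random-walk variances.
#' @param sweeps Coordinate-Gibbs sweeps per iteration.
#' @return A list of prior settings.
#' @export
steelhead_priors <- function(delta_sd = 5, init_sd = c(10, 10, 30),
                             a_obs = 1, b_obs = 0.01,
                             a_rw = 1, b_rw = 0.01, sweeps = 2L) {
  list(delta_sd = delta_sd, init_sd = init_sd, a_obs = a_obs, b_obs = b_obs,
       a_rw = a_rw, b_rw = b_rw, sweeps = as.integer(sweeps))
}

#' Fit the integrated Steelhead life-cycle model by MCMC
#'
#' Jointly samples the three linked regressions — logit marine survival, adult
#' female returns, and upstream run timing — each with a random-walk intercept,
#' by a conjugate Gibbs sampler with a joint 3-state FFBS. Adults and smolts
#' are scaled internally and results reported on the original scale. Years
#' with a missing adult count contribute no returns term and no timing term
#' (`ln S_t` is undefined there).
#'
#' @param data A [steelhead_series].
#' @param design_m Standardized marine-covariate [design_matrix] (survival).
#' @param design_t Standardized timing-covariate [design_matrix].
#' @param chains,iter,warmup_frac,thin,seed,profile As in [fit_community()].
#' @param priors See [steelhead_priors()].
#' @return An object of class `steelhead_fit` with draws of the coefficient
#'   and SD parameters, the three intercept paths, per-year log-likelihoods,
#'   and `neg_pred` (diagnostic count per draw of negative expected returns
#'   under the identity link).
#' @export
fit_steelhead <- function(data, design_m, design_t, chains = 2, iter = 1500,
                          warmup_frac = 0.5, thin = 1, seed = NULL,
                          priors = steelhead_priors(), profile = NULL) {
  stopifnot(inherits(data, "steelhead_series"))
  pf <- resolve_profile(profile, chains, iter)
  chains <- pf$chains; iter <- pf$iter
  T_ <- length(data$years)
  Xm <- design_m$values[match(data$years, design_m$brood_years), , drop = FALSE]
  Xt <- design_t$values[match(data$years, design_t$brood_years), , drop = FALSE]
  if (anyNA(Xm) || anyNA(Xt)) stop("designs must cover all years without gaps")
  sd_S <- pop_sd(data$adults[!is.na(data$adults)])
  sd_F <- pop_sd(data$smolts[!is.na(data$smolts)])
  Tbar <- mean(data$run_date, na.rm = TRUE)
  if (sd_S < 1e-12 || sd_F < 1e-12) stop("degenerate adult or smolt series")
  l <- data$logit_survival
  Sa <- data$adults / sd_S
  Tt <- data$run_date - Tbar
  F_ <- data$smolts / sd_F
  F_[is.na(F_)] <- 0
  lnS <- ifelse(!is.na(data$adults) & data$adults > 0, log(data$adults),
                NA_real_)
  n_warmup <- as.integer(floor(iter * warmup_frac))
  if (!is.null(seed)) set.seed(seed)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- gibbs_steelhead_cpp(l, Sa, Tt, F_, lnS, Xm, Xt,
                                     iter, n_warmup, as.integer(thin), priors)
  }
  n_keep <- nrow(res[[1]]$delta_m)
  chain_id <- rep(seq_len(chains), each = n_keep)
  bindm <- function(nm) do.call(rbind, lapply(res, `[[`, nm))
  delta_m <- bindm("delta_m"); colnames(delta_m) <- colnames(design_m$values)
  delta_T <- bindm("delta_T"); colnames(delta_T) <- colnames(design_t$values)
  sc <- bindm("scalars")
  sig <- bindm("sigma")
  # back-transform: adults were divided by sd_S, smolts by sd_F, dates
  # centered at Tbar; lnS and the covariates entered untransformed
  draws <- list(
    delta_m = delta_m,
    delta_S1 = sc[, 1] * sd_S,
    delta_S2 = sc[, 2] * sd_S / sd_F,
    delta_TS = sc[, 3],
    delta_T = delta_T,
    sigma = cbind(sigma_m = sig[, 1], sigma_S = sig[, 2] * sd_S,
                  sigma_T = sig[, 3], sigma_um = sig[, 4],
                  sigma_uS = sig[, 5] * sd_S, sigma_uT = sig[, 6])
  )
  st <- lapply(res, `[[`, "states")
  states <- array(0, c(n_keep * chains, T_, 3))
  for (ch in seq_len(chains))
    states[(ch - 1) * n_keep + seq_len(n_keep), , ] <- st[[ch]]
  draws$m0 <- states[, , 1]
  draws$S0 <- states[, , 2] * sd_S
  draws$T0 <- states[, , 3] + Tbar
  loglik <- bindm("loglik"); colnames(loglik) <- data$years
  structure(list(
    species = "steelhead", years = data$years, draws = draws,
    loglik = loglik, chain = chain_id, chains = chains, iter = iter,
    warmup = n_warmup, thin = thin, seed = seed, priors = priors,
    neg_pred = as.numeric(unlist(lapply(res, `[[`, "neg_pred"))),
    data = list(series = data, Xm = Xm, Xt = Xt, sd_S = sd_S, sd_F = sd_F,
                Tbar = Tbar, design_m = design_m, design_t = design_t)
  ), class = "steelhead_fit")
}

#' @export
print.steelhead_fit <- function(x, ...) {
  cat(sprintf("<steelhead_fit> %d years | %d chains x %d iter (%d retained draws)\n",
              length(x$years), x$chains, x$iter, length(x$chain)))
  cat(sprintf("negative expected-return draws (identity link): %.1f%% of draw-years\n",
              100 * mean(x$neg_pred) / length(x$years)))
  invisible(x)
}

#' @export
param_matrix.steelhead_fit <- function(fit, pars = c("beta", "delta", "sigma",
                                                     "ln_alpha")) {
  out <- cbind(fit$draws$delta_m, delta_S1 = fit$draws$delta_S1,
               delta_S2 = fit$draws$delta_S2, delta_TS = fit$draws$delta_TS,
               fit$draws$delta_T, fit$draws$sigma)
  colnames(out)[seq_len(ncol(fit$draws$delta_m))] <-
    paste0("delta_m[", colnames(fit$draws$delta_m), "]")
  j <- ncol(fit$draws$delta_m) + 3 + seq_len(ncol(fit$draws$delta_T))
  colnames(out)[j] <- paste0("delta_T[", colnames(fit$draws$delta_T), "]")
  attr(out, "chain") <- fit$chain
  out
}

#' Posterior draws of the predicted median run date path
#'
#' Returns the linear predictor of the timing submodel per draw and year:
#' `T0_t + delta_TS * ln(S_t) + delta_T . x_T`. Years without an observed
#' adult count (so `ln S_t` is undefined) are `NA`.
#'
#' @param fit A `steelhead_fit`.
#' @param include_covariates Include the `delta_T . x_T` term (default TRUE).
#' @return A draws x years matrix.
#' @export
run_timing_path <- function(fit, include_covariates = TRUE) {
  stopifnot(inherits(fit, "steelhead_fit"))
  adults <- fit$data$series$adults
  lnS <- ifelse(!is.na(adults) & adults > 0, log(adults), NA_real_)
  n <- nrow(fit$draws$T0)
  out <- fit$draws$T0 + outer(fit$draws$delta_TS, lnS)
  if (include_covariates)
    out <- out + fit$draws$delta_T %*% t(fit$data$Xt)
  colnames(out) <- fit$years
  out
}
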