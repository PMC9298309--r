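# MCMC convergence diagnostics and posterior predictive checks.

#' Potential scale reduction factor (split R-hat)
#'
#' Gelman-Rubin diagnostic computed after splitting each chain in half, so
#' within-chain trends are detected as well as between-chain disagreement.
#' Values near 1 indicate the chains sample a common distribution; values
#' above ~1.1 indicate non-convergence.
#'
#' @param x Numeric vector of draws (all chains concatenated).
#' @param chain Integer chain index per draw.
#' @return The PSRF (>= 1 up to floating point noise; `NA` for constant draws).
#' @export
psrf <- function(x, chain) {
  stopifnot(length(x) == length(chain))
  halves <- lapply(split(x, chain), function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  })
  segs <- unlist(halves, recursive = FALSE)
  n <- min(lengths(segs))
  if (n < 2L) stop("need at least 4 draws per chain")
  segs <- lapply(segs, function(v) v[seq_len(n)])
  m <- length(segs)
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < 1e-300) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size
#'
#' Autocorrelation-based multi-chain ESS: the total number of draws deflated
#' by the integrated autocorrelation time, with chain-mean disagreement
#' folded in through the pooled variance and the autocorrelation sum cut at
#' the first negative pair (Geyer's initial positive sequence).
#'
#' @inheritParams psrf
#' @return Estimated effective sample size (capped at the number of draws).
#' @export
ess <- function(x, chain) {
  stopifnot(length(x) == length(chain))
  ch <- split(x, chain)
  n <- min(lengths(ch))
  ch <- lapply(ch, function(v) v[seq_len(n)])
  m <- length(ch)
  if (n < 4L) stop("need at least 4 draws per chain")
  W <- mean(vapply(ch, var, numeric(1)))
  B_over_n <- if (m > 1) var(vapply(ch, mean, numeric(1))) else 0
  var_plus <- W * (n - 1) / n + B_over_n
  if (var_plus < 1e-300) return(NA_real_)
  max_lag <- min(n - 2L, 1000L)
  acov <- vapply(ch, function(v)
    as.numeric(acf(v, lag.max = max_lag, type = "covariance",
                   plot = FALSE, demean = TRUE)$acf),
    numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial positive sequence on paired sums
  s <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  ess_val <- m * n / (1 + 2 * s)
  min(ess_val, m * n)
}

#' Convergence report for a fitted model
#'
#' Per-parameter split-PSRF and effective sample size with pass/fail flags at
#' the conventional thresholds (PSRF < 1.1 and ESS > `ess_threshold`).
#'
#' @param fit A `community_fit` or `steelhead_fit` (at least 2 chains).
#' @param psrf_threshold,ess_threshold Flagging thresholds. The production
#'   sampling profile targets ESS > 1000; scale `ess_threshold` down for
#'   desk-scale runs.
#' @param pars Parameter groups, see [param_matrix()].
#' @return A data frame with columns `parameter`, `psrf`, `ess`, `converged`.
#' @export
convergence_report <- function(fit, psrf_threshold = 1.1, ess_threshold = 1000,
                               pars = c("beta", "delta", "sigma", "ln_alpha")) {
  m <- param_matrix(fit, pars = pars)
  chain <- attr(m, "chain")
  if (length(unique(chain)) < 2L)
    stop("convergence diagnostics require at least 2 chains")
  r <- apply(m, 2, psrf, chain = chain)
  e <- apply(m, 2, ess, chain = chain)
  data.frame(parameter = colnames(m), psrf = r, ess = e,
             converged = !is.na(r) & r < psrf_threshold & e > ess_threshold,
             row.names = NULL)
}

#' Posterior sign probability of a coefficient
#'
#' The posterior probability that a coefficient is greater than (and less
#' than) zero: the weight of evidence for a positive or negative association.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Named numeric vector `c(positive=, negative=)`.
#' @examples
#' sign_probability(c(-1, 2, 3, 4)) # positive 0.75
#' @export
sign_probability <- function(draws) {
  if (length(draws) == 0L) stop("no draws supplied")
  c(positive = mean(draws > 0), negative = mean(draws < 0))
}

#' Posterior predictive check
#'
#' Simulates replicate observations from the posterior predictive distribution
#' and reports, per observation, the central predictive interval and whether
#' the observed value falls inside it. For a well-specified model the
#' empirical coverage should match the nominal `prob` up to binomial error.
#'
#' Against the data the model was fitted to, interval coverage of a flexible
#' state-space model is typically above nominal (the fitted latent path
#' absorbs part of each residual); calibration is meaningful against
#' observations not used in fitting, supplied via `newdata`.
#'
#' @param fit A `community_fit` or `steelhead_fit`.
#' @param prob Central interval probability (default 0.8).
#' @param max_draws Cap on the number of posterior draws used.
#' @param newdata Optional replacement observation matrix (community fits:
#'   years x species, same shape as the fitted data) to score the predictive
#'   intervals against, e.g. a fresh replicate from the same process.
#' @param ... Unused.
#' @return A list with `table` (one row per observation: year, series,
#'   observed, lower, upper, covered) and `coverage` (overall fraction
#'   covered).
#' @export
posterior_predictive_check <- function(fit, prob = 0.8, max_draws = 500, ...) {
  UseMethod("posterior_predictive_check")
}

ppc_summarize <- function(tab, prob) {
  list(table = tab, coverage = mean(tab$covered), prob = prob)
}

#' @export
posterior_predictive_check.community_fit <- function(fit, prob = 0.8,
                                                     max_draws = 500,
                                                     newdata = NULL, ...) {
  dr <- fit$draws
  Yobs <- if (is.null(newdata)) fit$data$Y else {
    stopifnot(all(dim(newdata) == dim(fit$data$Y)))
    as.matrix(newdata)
  }
  n <- nrow(fit$loglik)
  sel <- if (n > max_draws) round(seq(1, n, length.out = max_draws)) else seq_len(n)
  T_ <- length(fit$years); d <- length(fit$species)
  alpha_tv <- fit$variant$alpha_tv
  X <- fit$data$X; Ss <- fit$data$Ss; s_scale <- fit$data$s_scale
  lo <- (1 - prob) / 2; hi <- 1 - lo
  yrep <- array(NA_real_, c(length(sel), T_, d))
  for (i in seq_along(sel)) {
    k <- sel[i]
    A <- if (alpha_tv) dr$ln_alpha[k, , ] else
      matrix(rep(dr$ln_alpha[k, ], each = T_), T_, d)
    if (!is.matrix(A)) A <- matrix(A, T_, d)
    beta_sc <- if (!is.null(dr$beta)) dr$beta[k, ] * s_scale else NULL
    MU <- A
    for (j in seq_len(d)) {
      bterm <- if (!is.null(beta_sc)) beta_sc[j] * Ss[, j] else
        dr$beta_t[k, , j] * s_scale[j] * Ss[, j]
      dcols <- grep(paste0("^", fit$species[j], ":"), colnames(dr$delta))
      xterm <- if (length(dcols)) X[[j]] %*% dr$delta[k, dcols] else 0
      MU[, j] <- A[, j] - bterm + xterm
    }
    L <- chol(fit$draws$Sigma_O[k, , ])
    yrep[i, , ] <- MU + matrix(rnorm(T_ * d), T_, d) %*% L
  }
  rows <- list()
  for (j in seq_len(d)) for (t in seq_len(T_)) {
    if (is.na(Yobs[t, j])) next
    q <- quantile(yrep[, t, j], c(lo, hi), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      year = fit$years[t], series = fit$species[j], observed = Yobs[t, j],
      lower = q[1], upper = q[2],
      covered = Yobs[t, j] >= q[1] & Yobs[t, j] <= q[2])
  }
  ppc_summarize(do.call(rbind, rows), prob)
}

#' @export
posterior_predictive_check.steelhead_fit <- function(fit, prob = 0.8,
                                                     max_draws = 500, ...) {
  dr <- fit$draws
  n <- nrow(dr$m0)
  sel <- if (n > max_draws) round(seq(1, n, length.out = max_draws)) else seq_len(n)
  sr <- fit$data$series
  T_ <- length(fit$years)
  lo <- (1 - prob) / 2; hi <- 1 - lo
  lnS <- ifelse(!is.na(sr$adults) & sr$adults > 0, log(sr$adults), NA_real_)
  Fv <- sr$smolts; Fv[is.na(Fv)] <- 0
  rows <- list()
  mk <- function(yobs, mu, sig, label) {
    for (t in seq_len(T_)) {
      if (is.na(yobs[t]) || anyNA(mu[, t])) next
      rep_t <- mu[, t] + rnorm(length(sel)) * sig
      q <- quantile(rep_t, c(lo, hi), names = FALSE)
      rows[[length(rows) + 1L]] <<- data.frame(
        year = fit$years[t], series = label, observed = yobs[t],
        lower = q[1], upper = q[2],
        covered = yobs[t] >= q[1] & yobs[t] <= q[2])
    }
  }
  m_mu <- dr$m0[sel, , drop = FALSE] + dr$delta_m[sel, , drop = FALSE] %*% t(fit$data$Xm)
  mk(sr$logit_survival, m_mu, dr$sigma[sel, "sigma_m"], "logit_survival")
  S_mu <- dr$S0[sel, , drop = FALSE] + dr$delta_S1[sel] * m_mu +
    outer(dr$delta_S2[sel], Fv)
  mk(sr$adults, S_mu, dr$sigma[sel, "sigma_S"], "adult_returns")
  T_mu <- dr$T0[sel, , drop = FALSE] + outer(dr$delta_TS[sel], lnS) +
    dr$delta_T[sel, , drop = FALSE] %*% t(fit$data$Xt)
  mk(sr$run_date, T_mu, dr$sigma[sel, "sigma_T"], "run_date")
  ppc_summarize(do.call(rbind, rows), prob)
}
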