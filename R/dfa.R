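# Dynamic factor analysis: a small number of shared latent random-walk trends
# with series-specific loadings and diagonal observation error, fitted by EM
# with a Kalman smoother. Used to impute missing years in count and covariate
# series by exploiting their covariation.
#
# Model, for series i = 1..n and year t = 1..T:
#   y[t] = Lambda f[t] + e[t],  e[t] ~ N(0, diag(r))
#   f[t] = f[t-1] + w[t],       w[t] ~ N(0, I_m),  f[1] ~ N(0, kappa I)
# Identifiability: Lambda lower-triangular with positive diagonal, unit
# process variance.

# Kalman filter + RTS smoother for the DFA model with missing observations.
# y: n x T with NA for missing. Returns smoothed means/vars, lag-one
# covariances and the exact log-likelihood (prediction error decomposition).
dfa_smoother <- function(y, Lambda, r, kappa = 5) {
  n <- nrow(y); T_ <- ncol(y); m <- ncol(Lambda)
  mp <- matrix(0, m, T_); Pp <- array(0, c(m, m, T_))   # predicted
  mf <- matrix(0, m, T_); Pf <- array(0, c(m, m, T_))   # filtered
  ll <- 0
  for (t in seq_len(T_)) {
    if (t == 1L) { mpre <- rep(0, m); Ppre <- diag(kappa, m) }
    else { mpre <- mf[, t - 1L]; Ppre <- Pf[, , t - 1L] + diag(m) }
    mp[, t] <- mpre; Pp[, , t] <- Ppre
    o <- which(!is.na(y[, t]))
    if (length(o) > 0L) {
      Z <- Lambda[o, , drop = FALSE]
      Ft <- Z %*% Ppre %*% t(Z) + diag(r[o], length(o))
      Ft <- (Ft + t(Ft)) / 2
      e <- y[o, t] - Z %*% mpre
      cF <- chol(Ft)
      ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(cF))) +
                          sum(backsolve(cF, e, transpose = TRUE)^2))
      K <- Ppre %*% t(Z) %*% chol2inv(cF)
      mf[, t] <- mpre + K %*% e
      Pf[, , t] <- Ppre - K %*% Z %*% Ppre
    } else {
      mf[, t] <- mpre; Pf[, , t] <- Ppre
    }
    Pf[, , t] <- (Pf[, , t] + t(Pf[, , t])) / 2
  }
  # RTS smoother with lag-one covariances
  ms <- mf; Ps <- Pf
  Plag <- array(0, c(m, m, T_))  # Cov(f_t, f_{t-1} | Y), slot t
  J <- array(0, c(m, m, T_))
  for (t in seq_len(T_ - 1L)) {
    Jt <- Pf[, , t] %*% solve(Pp[, , t + 1L])
    J[, , t] <- Jt
  }
  if (T_ > 1L) for (t in (T_ - 1L):1L) {
    Jt <- J[, , t]
    ms[, t] <- mf[, t] + Jt %*% (ms[, t + 1L] - mp[, t + 1L])
    Ps[, , t] <- Pf[, , t] + Jt %*% (Ps[, , t + 1L] - Pp[, , t + 1L]) %*% t(Jt)
    Ps[, , t] <- (Ps[, , t] + t(Ps[, , t])) / 2
    Plag[, , t + 1L] <- Ps[, , t + 1L] %*% t(Jt)
  }
  list(mean = ms, var = Ps, lag1 = Plag, loglik = ll,
       filtered = mf, predicted = mp)
}

#' Fit a dynamic factor analysis by EM
#'
#' Estimates shared latent random-walk trends and per-series loadings from a
#' matrix of (possibly gappy) standardized series, by
#' expectation-maximization with a Kalman smoother E-step. The loadings matrix
#' is constrained lower-triangular with positive diagonal and the trend
#' innovations have unit variance, the standard DFA identifiability
#' convention. Series are centered and scaled internally (constants stored).
#'
#' @param y Numeric matrix, series in rows, years in columns; `NA` marks
#'   missing cells.
#' @param n_trends Number of latent trends (<= number of series).
#' @param max_iter,tol EM stops when the relative log-likelihood improvement
#'   falls below `tol` (convergence) or after `max_iter` iterations
#'   (non-convergence, flagged with a warning).
#' @param kappa Prior variance of the initial trend value.
#'
#' @return An object of class `dfa_model` with elements `loadings` (n x m),
#'   `trends` (smoothed means, m x T), `trend_var`, `obs_var`, `loglik`
#'   (trace over iterations), `converged`, `center`, `scale`, `fitted`
#'   (on the original scale).
#' @examples
#' set.seed(1)
#' f <- cumsum(rnorm(60))
#' y <- rbind(0.9 * f + rnorm(60, sd = .3), 0.6 * f + rnorm(60, sd = .3))
#' m <- fit_dfa(y, n_trends = 1)
#' @export
fit_dfa <- function(y, n_trends = 1, max_iter = 2000, tol = 1e-6, kappa = 5) {
  y <- as.matrix(y)
  n <- nrow(y); T_ <- ncol(y); m <- as.integer(n_trends)
  if (m < 1L || m > n) stop("n_trends must be in 1..", n)
  if (any(rowSums(!is.na(y)) == 0L)) stop("a series is entirely missing")
  ctr <- apply(y, 1, mean, na.rm = TRUE)
  scl <- apply(y, 1, function(v) pop_sd(v[!is.na(v)]))
  if (any(scl < 1e-12)) stop("zero-variance series cannot enter a DFA")
  ys <- (y - ctr) / scl

  Lambda <- matrix(0, n, m)
  for (i in seq_len(n)) Lambda[i, seq_len(min(i, m))] <- 0.5
  r <- rep(0.5, n)
  llt <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sm <- dfa_smoother(ys, Lambda, r, kappa)
    llt <- c(llt, sm$loglik)
    if (it > 1L) {
      rel <- (llt[it] - llt[it - 1L]) / (abs(llt[it - 1L]) + 0.1)
      if (rel < -1e-8)
        warning("EM log-likelihood decreased by ", -rel, " at iteration ", it)
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    # E[f f'] per year
    EE <- lapply(seq_len(T_), function(t)
      sm$var[, , t] + tcrossprod(sm$mean[, t]))
    # M-step: loadings row-wise under the lower-triangular constraint
    for (i in seq_len(n)) {
      idx <- seq_len(min(i, m))
      obs <- which(!is.na(ys[i, ]))
      A <- matrix(0, length(idx), length(idx)); b <- numeric(length(idx))
      for (t in obs) {
        A <- A + EE[[t]][idx, idx, drop = FALSE]
        b <- b + ys[i, t] * sm$mean[idx, t]
      }
      Lambda[i, ] <- 0
      Lambda[i, idx] <- solve(A + diag(1e-10, length(idx)), b)
    }
    # M-step: observation variances given the new loadings
    for (i in seq_len(n)) {
      obs <- which(!is.na(ys[i, ]))
      li <- Lambda[i, ]
      ss <- sum(vapply(obs, function(t)
        ys[i, t]^2 - 2 * ys[i, t] * sum(li * sm$mean[, t]) +
          drop(li %*% EE[[t]] %*% li), numeric(1)))
      r[i] <- max(ss / length(obs), 1e-8)
    }
  }
  if (!converged)
    warning("DFA EM did not converge in ", max_iter, " iterations")
  # positive-diagonal sign convention (flip trend and its loading column)
  sm <- dfa_smoother(ys, Lambda, r, kappa)
  for (j in seq_len(m)) if (Lambda[j, j] < 0) {
    Lambda[, j] <- -Lambda[, j]
    sm$mean[j, ] <- -sm$mean[j, ]
  }
  fitted_std <- Lambda %*% sm$mean
  structure(list(
    n_trends = m, loadings = Lambda, trends = sm$mean, trend_var = sm$var,
    obs_var = r, loglik = llt, converged = converged,
    center = ctr, scale = scl, kappa = kappa,
    fitted = fitted_std * scl + ctr, dim = c(n, T_)
  ), class = "dfa_model")
}

#' @export
print.dfa_model <- function(x, ...) {
  cat(sprintf("<dfa_model> %d series x %d years, %d trend(s), logLik %.3f (%s)\n",
              x$dim[1], x$dim[2], x$n_trends, x$loglik[length(x$loglik)],
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Small-sample AIC of a fitted DFA
#'
#' Used to sweep over the number of trends when choosing a parsimonious
#' imputation model.
#'
#' @param model A `dfa_model`.
#' @return AICc value (smaller is better).
#' @export
dfa_aicc <- function(model) {
  stopifnot(inherits(model, "dfa_model"))
  n <- model$dim[1]; m <- model$n_trends
  k <- (n * m - m * (m - 1) / 2) + n
  ll <- model$loglik[length(model$loglik)]
  nobs <- n * model$dim[2]
  -2 * ll + 2 * k + 2 * k * (k + 1) / max(nobs - k - 1, 1)
}

#' Impute missing cells from a fitted DFA
#'
#' Missing cells are replaced by the smoothed expectation `Lambda f_t`
#' back-transformed to the original scale; observed cells are returned
#' untouched.
#'
#' @param model A `dfa_model` fitted on the same matrix.
#' @param y The series matrix the model was fitted to (series x years).
#' @return A list with `filled` (complete matrix) and `imputed` (logical flag
#'   matrix marking filled cells).
#' @export
dfa_impute <- function(model, y) {
  stopifnot(inherits(model, "dfa_model"))
  y <- as.matrix(y)
  if (!all(dim(y) == model$dim))
    stop("series matrix shape ", paste(dim(y), collapse = "x"),
         " does not match the fitted model ", paste(model$dim, collapse = "x"))
  flags <- is.na(y)
  filled <- y
  filled[flags] <- model$fitted[flags]
  list(filled = filled, imputed = flags)
}

#' Impute missing years across a catalog of covariate series
#'
#' Stacks the series into a matrix over their common year span, fits a DFA
#' with shared trends, and fills missing years with smoothed expectations.
#'
#' @param catalog A list of [cov_series] covering the same years.
#' @param n_trends Number of shared trends (default 2 for covariate blocks).
#' @param ... Passed to [fit_dfa()].
#' @return A list of [cov_series] with missing years filled (imputation
#'   recorded per-series in the `imputed` attribute), plus the fitted model as
#'   attribute `dfa`.
#' @export
impute_covariates <- function(catalog, n_trends = 2, ...) {
  stopifnot(length(catalog) >= 2L)
  yrs <- catalog[[1]]$years
  for (cv in catalog) if (!identical(cv$years, yrs))
    stop("all series must cover the same years")
  Y <- do.call(rbind, lapply(catalog, function(cv) {
    v <- cv$values; v[cv$missing] <- NA_real_; v
  }))
  model <- fit_dfa(Y, n_trends = n_trends, ...)
  filled <- dfa_impute(model, Y)
  out <- lapply(seq_along(catalog), function(i) {
    cv <- cov_series(catalog[[i]]$name, yrs, filled$filled[i, ])
    attr(cv, "imputed") <- filled$imputed[i, ]
    cv
  })
  names(out) <- vapply(catalog, `[[`, character(1), "name")
  attr(out, "dfa") <- model
  out
}
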