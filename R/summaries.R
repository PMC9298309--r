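# Headline derived quantities from posterior draws: regime percent changes,
# marginal covariate effects, run-timing shifts, and cross-species
# productivity correlations.

#' Productivity regime windows
#'
#' Year windows delimiting the descriptive productivity regimes: an early
#' regime, a compensatory regime of elevated intrinsic productivity, and a
#' recent declining regime. Boundaries are configuration, not constants.
#'
#' @param early,compensatory,declining Length-2 numeric ranges (inclusive);
#'   `Inf` is allowed as an open end.
#' @return A named list of class `regime_windows`.
#' @export
regime_windows <- function(early = c(1976, 1990),
                           compensatory = c(1991, 2009),
                           declining = c(2010, Inf)) {
  w <- list(early = early, compensatory = compensatory, declining = declining)
  for (nm in names(w)) if (length(w[[nm]]) != 2L || w[[nm]][1] > w[[nm]][2])
    stop("window '", nm, "' must be an ordered length-2 range")
  ends <- vapply(w, `[`, numeric(1), 2)
  starts <- vapply(w, `[`, numeric(1), 1)
  if (any(diff(starts) <= 0) || any(starts[-1] <= ends[-3]))
    stop("windows must be ordered and non-overlapping")
  structure(w, class = "regime_windows")
}

summarize_draws_ci <- function(x, prob = 0.8) {
  lo <- (1 - prob) / 2
  q <- quantile(x, c(lo, 1 - lo), names = FALSE, na.rm = TRUE)
  list(mean = mean(x, na.rm = TRUE), lo80 = q[1], hi80 = q[2])
}

#' Percent change between two values, per posterior draw
#'
#' `100 * (v_b / v_a - 1)` applied draw-wise, the low-level kernel behind
#' [percent_change()].
#'
#' @param v_a,v_b Numeric draw vectors (recycled against each other).
#' @return Numeric vector of percent changes.
#' @examples
#' pct_change_draws(2, 3) # +50
#' @export
pct_change_draws <- function(v_a, v_b) 100 * (v_b / v_a - 1)

#' Posterior percent change in intrinsic productivity between two years
#'
#' For each posterior draw, the percent change in a species' intrinsic
#' productivity between `year_a` and `year_b`, on the natural `alpha` scale
#' (recruits per spawner at low density: `100*(exp(a_b)/exp(a_a) - 1)`, the
#' default) or on the `ln_alpha` scale (`100*(a_b/a_a - 1)`). On the log scale
#' the ratio is ill-defined when the path crosses zero; such draws are counted
#' in `n_flagged`.
#'
#' @param fit A `community_fit` with a time-varying intercept.
#' @param species Species name.
#' @param year_a,year_b Years within the fitted path.
#' @param scale `"alpha"` or `"ln_alpha"`.
#' @param prob Credible-interval probability (default 0.8, central).
#' @return A list: `mean`, `lo80`, `hi80`, `draws`, `scale`, `n_flagged`.
#' @export
percent_change <- function(fit, species, year_a, year_b,
                           scale = c("alpha", "ln_alpha"), prob = 0.8) {
  scale <- match.arg(scale)
  la <- fit$draws$ln_alpha
  if (length(dim(la)) != 3)
    stop("percent_change over years requires a time-varying intercept fit")
  j <- match(species, fit$species)
  ia <- match(year_a, fit$years); ib <- match(year_b, fit$years)
  if (is.na(j)) stop("unknown species '", species, "'")
  if (is.na(ia) || is.na(ib)) stop("years outside the fitted path")
  a <- la[, ia, j]; b <- la[, ib, j]
  n_flagged <- 0L
  if (scale == "alpha") {
    d <- pct_change_draws(exp(a), exp(b))
  } else {
    n_flagged <- sum(sign(a) != sign(b) | abs(a) < 1e-12)
    d <- pct_change_draws(a, b)
    d[abs(a) < 1e-12] <- NA_real_
  }
  c(summarize_draws_ci(d, prob),
    list(draws = d, scale = scale, n_flagged = n_flagged))
}

#' Marginal percent effect of a covariate shift
#'
#' `100 * (exp(delta * dx) - 1)` per draw: the all-else-equal percent change in
#' recruits-per-spawner implied by moving a standardized covariate by `dx`
#' units, e.g. from its 1976 value to its 2015 value.
#'
#' @param delta_draws Posterior draws of the coefficient.
#' @param dx Covariate shift in standardized units.
#' @param prob Credible-interval probability.
#' @return A list: `mean`, `lo80`, `hi80`, `draws`, `dx`.
#' @examples
#' marginal_effect_pct(-1, 2)$mean # 100*(exp(-2)-1) ~ -86.5
#' @export
marginal_effect_pct <- function(delta_draws, dx, prob = 0.8) {
  d <- 100 * (exp(delta_draws * dx) - 1)
  c(summarize_draws_ci(d, prob), list(draws = d, dx = dx))
}

#' Marginal effect of the change in a covariate between two years
#'
#' Looks up the standardized covariate values at two years in the species'
#' fitted design matrix (which must carry standardization metadata) and
#' summarizes [marginal_effect_pct()] over the posterior of that species'
#' coefficient. With the cumulative-logging column this is the predicted
#' marginal effect of logging intensification, all else equal.
#'
#' @param fit A `community_fit`.
#' @param species Species name.
#' @param covariate Design-matrix column name.
#' @param year_a,year_b Years defining the shift (defaults: first and last
#'   fitted year).
#' @param prob Credible-interval probability.
#' @return As [marginal_effect_pct()].
#' @export
logging_marginal_effect <- function(fit, species, covariate = "logging",
                                    year_a = NULL, year_b = NULL, prob = 0.8) {
  j <- match(species, fit$species)
  if (is.na(j)) stop("unknown species '", species, "'")
  dmj <- fit$data$designs[[j]]
  if (is.null(dmj$standardization))
    stop("design matrix for ", species, " carries no standardization metadata")
  if (!covariate %in% colnames(dmj$values))
    stop("no covariate '", covariate, "' for ", species)
  if (is.null(year_a)) year_a <- min(fit$years)
  if (is.null(year_b)) year_b <- max(fit$years)
  ia <- match(year_a, dmj$brood_years); ib <- match(year_b, dmj$brood_years)
  if (is.na(ia) || is.na(ib)) stop("years outside the design matrix")
  dx <- dmj$values[ib, covariate] - dmj$values[ia, covariate]
  col <- paste0(species, ":", covariate)
  marginal_effect_pct(fit$draws$delta[, col], dx, prob = prob)
}

#' Run-timing shift between regimes
#'
#' Per posterior draw, the difference between within-window means of the
#' predicted median run date, for each later regime against each earlier one.
#' Invariant to adding a constant to all dates.
#'
#' @param T_draws Draws x years matrix of run dates (e.g.
#'   [run_timing_path()]); column names are years.
#' @param windows A [regime_windows()].
#' @param prob Credible-interval probability.
#' @return A data frame with one row per window pair: `comparison`,
#'   `mean_days`, `lo80`, `hi80` (negative = earlier migration in the later
#'   regime).
#' @export
regime_timing_shift <- function(T_draws, windows = regime_windows(),
                                prob = 0.8) {
  years <- as.numeric(colnames(T_draws))
  if (anyNA(years)) stop("T_draws must have years as column names")
  wmeans <- lapply(windows, function(w) {
    idx <- which(years >= w[1] & years <= w[2])
    if (length(idx) == 0L) stop("empty regime window [",
                                w[1], ", ", w[2], "]")
    rowMeans(T_draws[, idx, drop = FALSE], na.rm = TRUE)
  })
  nm <- names(windows)
  rows <- list()
  for (i in seq_along(nm)) for (k in seq_along(nm)) {
    if (k <= i) next
    d <- wmeans[[k]] - wmeans[[i]]
    s <- summarize_draws_ci(d, prob)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = paste0(nm[k], " - ", nm[i]),
      mean_days = s$mean, lo80 = s$lo80, hi80 = s$hi80)
  }
  do.call(rbind, rows)
}

#' Posterior mean correlation between species' productivity trajectories
#'
#' For each posterior draw, the Pearson correlation between every pair of
#' species' `ln alpha` time paths, averaged over draws. Draws in which a path
#' is constant have an undefined correlation for that pair and are excluded
#' (counted in `n_excluded`).
#'
#' @param fit A `community_fit` with time-varying intercepts.
#' @return A list: `correlation` (species x species posterior-mean matrix,
#'   unit diagonal) and `n_excluded` (pairwise matrix of excluded draws).
#' @export
productivity_correlations <- function(fit) {
  la <- fit$draws$ln_alpha
  if (length(dim(la)) != 3)
    stop("requires a time-varying intercept fit")
  if (dim(la)[2] < 3L) stop("need at least 3 common years")
  d <- dim(la)[3]; n <- dim(la)[1]
  cm <- matrix(1, d, d, dimnames = list(fit$species, fit$species))
  nex <- matrix(0L, d, d, dimnames = list(fit$species, fit$species))
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) {
    r <- vapply(seq_len(n), function(k) {
      a <- la[k, , i]; b <- la[k, , j]
      if (pop_sd(a) < 1e-12 || pop_sd(b) < 1e-12) NA_real_ else cor(a, b)
    }, numeric(1))
    nex[i, j] <- nex[j, i] <- sum(is.na(r))
    cm[i, j] <- cm[j, i] <- mean(r, na.rm = TRUE)
  }
  list(correlation = cm, n_excluded = nex)
}

#' Long-format summary table of a fitted community model
#'
#' One row per (species, summary) with posterior mean and central 80% CI:
#' density dependence, covariate effects with sign probabilities, and regime
#' percent changes where a time-varying path is available.
#'
#' @param fit A `community_fit`.
#' @param windows A [regime_windows()] used for percent-change anchors.
#' @return A data frame with columns `species`, `summary`, `mean`, `lo80`,
#'   `hi80`, `prob_positive`.
#' @export
summary_table <- function(fit, windows = regime_windows()) {
  rows <- list()
  add <- function(species, nm, draws) {
    s <- summarize_draws_ci(draws)
    rows[[length(rows) + 1L]] <<- data.frame(
      species = species, summary = nm, mean = s$mean, lo80 = s$lo80,
      hi80 = s$hi80, prob_positive = mean(draws > 0))
  }
  for (j in seq_along(fit$species)) {
    sp <- fit$species[j]
    if (!is.null(fit$draws$beta)) add(sp, "beta", fit$draws$beta[, j])
    cols <- grep(paste0("^", sp, ":"), colnames(fit$draws$delta), value = TRUE)
    for (cl in cols) add(sp, paste0("delta:", sub("^.*:", "", cl)),
                         fit$draws$delta[, cl])
    if (length(dim(fit$draws$ln_alpha)) == 3) {
      ya <- max(min(fit$years), windows$early[1])
      yb <- min(max(fit$years), windows$compensatory[1])
      pc <- percent_change(fit, sp, ya, yb)
      add(sp, sprintf("pct_change_alpha_%d_%d", ya, yb), pc$draws)
    }
  }
  do.call(rbind, rows)
}
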