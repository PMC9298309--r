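#' Cumulative logging footprint over a sliding window
#'
#' The running total of annual logged area over the preceding `window_years`
#' years (inclusive of the current year). Hydrological and habitat impacts of
#' clear-cut forestry integrate over one to three decades, so the watershed
#' pressure index at year t is the area cut in `[t - window_years + 1, t]`.
#'
#' Years whose window would extend before the start of the series are not
#' returned: the series must cover the full window (supply recorded pre-series
#' harvest by extending the input backwards). Silent zero-filling would
#' understate early cumulative harvest.
#'
#' @param annual_logged_area A [cov_series] of annual logged area (km^2),
#'   non-negative, no missing years.
#' @param window_years Window length in years (default 15).
#'
#' @return A [cov_series] named `"<name>_cum<window>"` covering the years with
#'   a complete window.
#' @examples
#' x <- cov_series("logged_area", 1990:1992, c(2, 3, 5))
#' cumulative_logging(x, 2)$values # 5, 8
#' @export
cumulative_logging <- function(annual_logged_area, window_years = 15) {
  cov <- annual_logged_area
  stopifnot(inherits(cov, "cov_series"))
  window_years <- as.integer(window_years)
  if (window_years < 1L) stop("window_years must be >= 1")
  if (any(cov$missing)) stop("logged-area series has missing years; impute first")
  if (any(cov$values < 0)) stop("negative annual logged areas")
  n <- length(cov$years)
  if (n < window_years)
    stop("series covers ", n, " years; window of ", window_years,
         " requires at least that many (extend backwards with recorded pre-series harvest)")
  cs <- cumsum(cov$values)
  idx <- window_years:n
  out <- cs[idx] - c(0, cs)[idx - window_years + 1]
  cov_series(paste0(cov$name, "_cum", window_years), cov$years[idx], out)
}

# rearing/ocean spans per age; freshwater age a covers brood year t through
# the year before out-migration (t..t+a-1; just {t} for fry migrants, a = 0).
# The marine phase covers out-migration year through return year inclusive.
phase_span <- function(phase, brood_year, fw_age, marine_age = NULL) {
  switch(phase,
    freshwater = if (fw_age == 0L) c(brood_year, brood_year)
                 else c(brood_year, brood_year + fw_age - 1L),
    marine = c(brood_year + fw_age, brood_year + fw_age + marine_age),
    stop("unknown phase '", phase, "'")
  )
}

#' Lag an annual covariate onto brood years by age structure
#'
#' Converts a calendar-year environmental series into a brood-year series by
#' averaging over the years each cohort actually experienced, weighted by the
#' species' proportions-at-age. A brood-year t cohort with freshwater age a
#' rears in years t..t+a-1 (the brood year through the year before smolt
#' out-migration; fry migrants, age 0, experience only year t). For the marine
#' phase, a cohort with freshwater age a and marine age m is at sea in years
#' t+a .. t+a+m (out-migration through return, inclusive), and the weights are
#' the product of freshwater and marine proportions-at-age.
#'
#' @param cov A [cov_series] on calendar years (no missing years within the
#'   lagged spans).
#' @param ages An [age_profile].
#' @param phase `"freshwater"` or `"marine"`.
#' @param brood_years Integer vector of brood years to produce.
#'
#' @return A [cov_series] indexed by brood year.
#' @examples
#' ap <- age_profile("sh", c(`1` = 0.5, `2` = 0.5), c(`2` = 1))
#' cv <- cov_series("temp", 1975:1985, 1:11)
#' lag_to_brood_year(cv, ap, "freshwater", 1975:1980)
#' @export
lag_to_brood_year <- function(cov, ages, phase = c("freshwater", "marine"),
                              brood_years) {
  stopifnot(inherits(cov, "cov_series"), inherits(ages, "age_profile"))
  phase <- match.arg(phase)
  brood_years <- as.integer(brood_years)
  fw <- ages$freshwater_age_props
  ma <- ages$marine_age_props
  vals <- vapply(brood_years, function(t) {
    if (phase == "freshwater") {
      w <- 0
      for (i in seq_along(fw)) {
        a <- as.integer(names(fw)[i])
        sp <- phase_span("freshwater", t, a)
        w <- w + fw[i] * cov_span_mean(cov, sp[1], sp[2])
      }
      w
    } else {
      w <- 0
      for (i in seq_along(fw)) for (j in seq_along(ma)) {
        a <- as.integer(names(fw)[i])
        m <- as.integer(names(ma)[j])
        sp <- phase_span("marine", t, a, m)
        w <- w + fw[i] * ma[j] * cov_span_mean(cov, sp[1], sp[2])
      }
      w
    }
  }, numeric(1))
  cov_series(paste0(cov$name, "_", substr(phase, 1, 2), "lag"),
             brood_years, vals)
}

#' Seal-predation exposure of a cohort
#'
#' Smolts and returning adults both pass through coastal waters where harbour
#' seals forage, so a cohort's exposure is the sum of seal densities in its
#' out-migration year and its subsequent spawning (return) year. Juveniles
#' whose body size at out-migration is below the seal predation window (Pink
#' Salmon fry) are exposed only as returning adults (`adult_only = TRUE`).
#'
#' @param seals A [cov_series] of seal densities.
#' @param outmigration_year,spawn_year Calendar years of the cohort's smolt
#'   out-migration and adult return.
#' @param adult_only If `TRUE`, count only the spawning-year exposure.
#'
#' @return A single numeric exposure value.
#' @examples
#' s <- cov_series("seals", 2000:2003, c(1, 2, 3, 4))
#' seal_exposure(s, 2000, 2003)              # 5
#' seal_exposure(s, 2000, 2003, adult_only = TRUE) # 4
#' @export
seal_exposure <- function(seals, outmigration_year, spawn_year,
                          adult_only = FALSE) {
  stopifnot(inherits(seals, "cov_series"))
  if (adult_only) cov_at(seals, spawn_year)
  else cov_at(seals, outmigration_year) + cov_at(seals, spawn_year)
}

#' Collapse two collinear indices by principal components
#'
#' Replaces a collinear pair of (standardized) annual indices, such as seal
#' density and North Pacific salmon abundance, by their two principal-component
#' score series. The first axis (`pc1`, "ocean interactions") carries the
#' shared variation; signs are fixed so that `pc1` is positively associated
#' with the first input and `pc2` is positively associated with the first
#' input and negatively with the second. Total variance is conserved.
#'
#' @param a,b [cov_series] on identical years, standardized, no missing.
#'
#' @return A list with `pc1`, `pc2` ([cov_series]) and the 2x2 `loadings`
#'   matrix (columns = components) plus `var_explained`.
#' @examples
#' yrs <- 1976:2015
#' a <- standardize(cov_series("seals", yrs, sin(yrs / 3)))
#' b <- standardize(cov_series("npsa", yrs, sin(yrs / 3) + rnorm(40, sd = .4)))
#' collapse_collinear_pca(a, b)$var_explained
#' @export
collapse_collinear_pca <- function(a, b) {
  stopifnot(inherits(a, "cov_series"), inherits(b, "cov_series"))
  if (length(a$years) != length(b$years) || any(a$years != b$years))
    stop("series '", a$name, "' and '", b$name, "' must share the same years")
  if (any(a$missing) || any(b$missing)) stop("series must have no missing years")
  M <- cbind(a$values, b$values)
  cc <- crossprod(scale(M, center = TRUE, scale = FALSE)) / (nrow(M) - 1)
  eg <- eigen(cc, symmetric = TRUE)
  V <- eg$vectors
  scores <- scale(M, center = TRUE, scale = FALSE) %*% V
  # sign convention: pc1 loads positively on a; pc2 positively on a,
  # negatively on b (when the components allow it)
  if (V[1, 1] < 0) { V[, 1] <- -V[, 1]; scores[, 1] <- -scores[, 1] }
  if (V[1, 2] < 0 || (V[1, 2] == 0 && V[2, 2] > 0)) {
    V[, 2] <- -V[, 2]; scores[, 2] <- -scores[, 2]
  }
  list(
    pc1 = cov_series("ocean_interactions", a$years, scores[, 1]),
    pc2 = cov_series("ocean_pca2", a$years, scores[, 2]),
    loadings = structure(V, dimnames = list(c(a$name, b$name), c("pc1", "pc2"))),
    var_explained = eg$values / sum(eg$values)
  )
}

#' Brood-year design matrix of environmental covariates
#'
#' A per-species matrix of brood-year-aligned covariate values, one column per
#' covariate. Standardization constants (per-column mean and population SD) are
#' attached by [standardize()] so effect sizes are comparable across covariates
#' and the transform is exactly invertible.
#'
#' @param species Single string.
#' @param brood_years Integer vector.
#' @param values Numeric matrix (brood year x covariate) with column names.
#'
#' @return An object of class `design_matrix`.
#' @export
design_matrix <- function(species, brood_years, values) {
  values <- as.matrix(values)
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("covariate columns must be named")
  if (nrow(values) != length(brood_years))
    stop("values must have one row per brood year")
  structure(list(species = species, brood_years = as.integer(brood_years),
                 values = values, standardization = NULL),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s: %d brood years x %d covariates (%s)\n",
              x$species, nrow(x$values), ncol(x$values),
              if (is.null(x$standardization)) "raw" else "standardized"))
  invisible(x)
}

#' Standardize covariates to zero mean and unit variance
#'
#' Centers and scales using the population SD (denominator n), so that effect
#' sizes on standardized covariates are directly comparable; the means and SDs
#' used are stored for exact inverse transformation. Binary indicator
#' covariates are standardized like continuous ones.
#'
#' @param x A `design_matrix` or `cov_series`.
#' @param ... Unused.
#' @return The same class of object, standardized; for design matrices the
#'   `standardization` field holds the per-column `mean` and `sd` used.
#' @export
standardize <- function(x, ...) UseMethod("standardize")

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' @rdname standardize
#' @export
standardize.design_matrix <- function(x, ...) {
  if (anyNA(x$values)) stop("design matrix has missing entries; impute first")
  mu <- colMeans(x$values)
  sdv <- apply(x$values, 2, pop_sd)
  zero <- sdv < 1e-12
  if (any(zero))
    stop("zero-variance column(s): ", paste(colnames(x$values)[zero], collapse = ", "))
  x$values <- sweep(sweep(x$values, 2, mu), 2, sdv, "/")
  x$standardization <- list(mean = mu, sd = sdv)
  x
}

#' @rdname standardize
#' @export
standardize.cov_series <- function(x, ...) {
  ok <- !x$missing
  if (!any(ok)) stop("all-missing series '", x$name, "'")
  mu <- mean(x$values[ok]); sdv <- pop_sd(x$values[ok])
  if (sdv < 1e-12) stop("zero-variance column: ", x$name)
  x$values[ok] <- (x$values[ok] - mu) / sdv
  attr(x, "standardization") <- list(mean = mu, sd = sdv)
  x
}

#' Undo standardization of a design matrix
#'
#' @param x A standardized `design_matrix`.
#' @return The design matrix on the original scale.
#' @export
unstandardize <- function(x) {
  stopifnot(inherits(x, "design_matrix"))
  st <- x$standardization
  if (is.null(st)) stop("design matrix carries no standardization constants")
  x$values <- sweep(sweep(x$values, 2, st$sd, "*"), 2, st$mean, "+")
  x$standardization <- NULL
  x
}

#' Variance inflation factors of a design matrix
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing column j on all other columns.
#' Values above `threshold` (default 4, the usual screening cut for ecological
#' regressions) are flagged; a perfectly collinear column is reported as
#' infinite and flagged.
#'
#' @param dm A `design_matrix` (or plain matrix) with at least two columns and
#'   more rows than columns.
#' @param threshold Warn flag cutoff.
#' @return A data frame with columns `covariate`, `vif`, `flag`.
#' @export
vif_screen <- function(dm, threshold = 4) {
  X <- if (inherits(dm, "design_matrix")) dm$values else as.matrix(dm)
  if (ncol(X) < 2L) stop("need at least two columns")
  if (nrow(X) <= ncol(X)) stop("need more rows than columns")
  if (anyNA(X)) stop("missing entries; impute first")
  if (all(apply(X, 2, pop_sd) < 1e-12)) stop("singular design: all columns constant")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    res <- sum(fit$residuals^2)
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot < 1e-12) stop("singular design: constant column ", colnames(X)[j])
    r2 <- 1 - res / tot
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = colnames(X), vif = vifs,
             flag = !is.finite(vifs) | vifs > threshold,
             row.names = NULL)
}
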