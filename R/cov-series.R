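#' Annual covariate series
#'
#' A named annual time series of an environmental covariate (climate index,
#' logged area, seal density, ...) on consecutive calendar years, with an
#' explicit missingness flag per year. All covariate-construction operations in
#' the package consume and return this container.
#'
#' @param name Single string identifying the covariate.
#' @param years Integer vector of consecutive calendar years (step 1, strictly
#'   increasing).
#' @param values Numeric vector, one value per year. `NA` is allowed only where
#'   `missing` is `TRUE`.
#' @param missing Logical vector flagging missing years. Defaults to
#'   `is.na(values)`.
#'
#' @return An object of class `cov_series`: a list with elements `name`,
#'   `years`, `values`, `missing`.
#' @examples
#' logged <- cov_series("logged_area", 1990:1992, c(2, 3, 5))
#' cumulative_logging(logged, window_years = 2)
#' @export
cov_series <- function(name, years, values, missing = is.na(values)) {
  stopifnot(is.character(name), length(name) == 1L)
  years <- as.integer(years)
  if (length(years) == 0L) stop("empty covariate series '", name, "'")
  if (length(values) != length(years) || length(missing) != length(years))
    stop("years, values and missing must have equal length")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be consecutive integers (step 1)")
  values <- as.numeric(values)
  if (any(!missing & !is.finite(values)))
    stop("non-finite values at non-missing years in '", name, "'")
  structure(list(name = name, years = years, values = values,
                 missing = as.logical(missing)),
            class = "cov_series")
}

#' @export
print.cov_series <- function(x, ...) {
  cat(sprintf("<cov_series> %s: %d-%d (%d years, %d missing)\n",
              x$name, min(x$years), max(x$years), length(x$years),
              sum(x$missing)))
  invisible(x)
}

#' @export
length.cov_series <- function(x) length(x$years)

# value at a single year, erroring with the year named
cov_at <- function(cov, year) {
  i <- match(year, cov$years)
  if (is.na(i))
    stop("covariate '", cov$name, "' does not cover year ", year)
  if (cov$missing[i])
    stop("covariate '", cov$name, "' is missing at year ", year)
  cov$values[i]
}

# mean over an inclusive span of years
cov_span_mean <- function(cov, from, to) {
  mean(vapply(seq.int(from, to), function(y) cov_at(cov, y), numeric(1)))
}

#' Species age-structure profile
#'
#' Proportions-at-age for the freshwater (brood year to smolt out-migration)
#' and marine (out-migration to spawning return) phases of a species' life
#' cycle, used to lag annual covariates onto brood years.
#'
#' @param species Single string.
#' @param freshwater_age_props Named numeric vector; names are integer ages
#'   (years spent rearing in freshwater, 0 for fry migrants), values are
#'   proportions summing to 1.
#' @param marine_age_props Named numeric vector of marine ages (years at sea),
#'   proportions summing to 1.
#'
#' @return An object of class `age_profile`.
#' @examples
#' age_profile("coho", c(`1` = 1), c(`2` = 1))
#' @export
age_profile <- function(species, freshwater_age_props, marine_age_props) {
  check_props <- function(p, what) {
    if (is.null(names(p)) || anyNA(suppressWarnings(as.integer(names(p)))))
      stop(what, " proportions must be named by integer age")
    if (any(p < 0)) stop(what, " proportions must be non-negative")
    if (abs(sum(p) - 1) > 1e-9)
      stop(what, " proportions must sum to 1 (got ", sum(p), ")")
    p
  }
  structure(list(
    species = species,
    freshwater_age_props = check_props(freshwater_age_props, "freshwater"),
    marine_age_props = check_props(marine_age_props, "marine")
  ), class = "age_profile")
}

#' @export
print.age_profile <- function(x, ...) {
  cat(sprintf("<age_profile> %s  freshwater ages: %s  marine ages: %s\n",
              x$species,
              paste0(names(x$freshwater_age_props), collapse = ","),
              paste0(names(x$marine_age_props), collapse = ",")))
  invisible(x)
}
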