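# Plain-text interchange: long-format covariate CSVs, brood tables, the
# Steelhead life-cycle CSV, design-matrix exports with standardization
# sidecars, and whole-dataset dumps.

#' Read a long-format covariate CSV
#'
#' Expects columns `name`, `year`, `value`; each covariate becomes a
#' [cov_series] over the full span of its years, with absent or `NA` years
#' flagged missing.
#'
#' @param path CSV file path.
#' @return Named list of [cov_series].
#' @export
read_covariates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "year", "value") %in% names(df)))
  out <- lapply(split(df, df$name), function(g) {
    yrs <- seq(min(g$year), max(g$year))
    v <- rep(NA_real_, length(yrs))
    v[match(g$year, yrs)] <- g$value
    cov_series(g$name[1], yrs, v)
  })
  out[unique(df$name)]
}

#' Write a covariate catalog as a long-format CSV
#'
#' @param catalog Named list of [cov_series].
#' @param path Output file.
#' @export
write_covariates_csv <- function(catalog, path) {
  df <- do.call(rbind, lapply(catalog, function(cv)
    data.frame(name = cv$name, year = cv$years,
               value = ifelse(cv$missing, NA_real_, cv$values))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read age-structure profiles from CSV
#'
#' Expects columns `species`, `phase` (`freshwater`/`marine`), `age`,
#' `proportion`.
#'
#' @param path CSV file path.
#' @return Named list of [age_profile].
#' @export
read_age_structure_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "phase", "age", "proportion") %in% names(df)))
  lapply(split(df, df$species), function(g) {
    grab <- function(ph) {
      gg <- g[g$phase == ph, ]
      setNames(gg$proportion, gg$age)
    }
    age_profile(g$species[1], grab("freshwater"), grab("marine"))
  })
}

#' Read per-species brood tables from CSV
#'
#' Expects columns `species`, `brood_year`, `spawners`, `recruits`, and
#' optionally `recruit_definition`.
#'
#' @param path CSV file path.
#' @return Named list of [brood_table].
#' @export
read_brood_table_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "brood_year", "spawners", "recruits") %in%
                  names(df)))
  lapply(split(df, df$species), function(g) {
    g <- g[order(g$brood_year), ]
    rd <- if ("recruit_definition" %in% names(g)) g$recruit_definition[1]
          else "smolt_outmigrants"
    brood_table(g$species[1], g$brood_year, g$spawners, g$recruits, rd)
  })
}

#' Write brood tables to CSV
#'
#' @param broods Named list of [brood_table].
#' @param path Output file.
#' @export
write_brood_table_csv <- function(broods, path) {
  df <- do.call(rbind, lapply(broods, function(bt)
    data.frame(species = bt$species, brood_year = bt$brood_years,
               spawners = bt$spawners, recruits = bt$recruits,
               recruit_definition = bt$recruit_definition)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read the Steelhead life-cycle CSV
#'
#' Expects columns `year` (or `brood_year`), `smolts`, `adult_females`,
#' `median_run_date`.
#'
#' @param path CSV file path.
#' @return A [steelhead_series].
#' @export
read_steelhead_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  ycol <- if ("year" %in% names(df)) "year" else "brood_year"
  stopifnot(all(c(ycol, "smolts", "adult_females", "median_run_date") %in%
                  names(df)))
  df <- df[order(df[[ycol]]), ]
  steelhead_series(df[[ycol]], df$smolts, df$adult_females,
                   df$median_run_date)
}

#' Write a Steelhead life-cycle series to CSV
#'
#' @param series A [steelhead_series].
#' @param path Output file.
#' @export
write_steelhead_csv <- function(series, path) {
  write.csv(data.frame(year = series$years, smolts = series$smolts,
                       adult_females = series$adults,
                       median_run_date = series$run_date),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a design matrix with a standardization/VIF sidecar
#'
#' Writes the (standardized) design matrix as CSV and a JSON sidecar holding
#' the per-column standardization constants and the VIF screening report.
#'
#' @param dm A standardized [design_matrix].
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_design_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "design_matrix"))
  df <- data.frame(brood_year = dm$brood_years, dm$values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(species = dm$species,
                  standardization = lapply(dm$standardization, as.list),
                  vif = if (ncol(dm$values) >= 2)
                    vif_screen(dm) else NULL)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a complete synthetic dataset to a directory
#'
#' Writes `covariates.csv`, `brood_tables.csv`, `steelhead.csv`,
#' `weather.csv`, per-species design matrices with sidecars, and a
#' `truth.json` of the generating parameters.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_covariates_csv(dataset$covariates, file.path(dir, "covariates.csv"))
  write_brood_table_csv(dataset$broods, file.path(dir, "brood_tables.csv"))
  write_steelhead_csv(dataset$steelhead$series, file.path(dir, "steelhead.csv"))
  write.csv(dataset$weather, file.path(dir, "weather.csv"), row.names = FALSE)
  for (s in names(dataset$designs))
    write_design_matrix(dataset$designs[[s]],
                        file.path(dir, paste0("design_", s, ".csv")))
  truth <- dataset$truth
  truth$community$ln_alpha <- as.data.frame(truth$community$ln_alpha)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
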