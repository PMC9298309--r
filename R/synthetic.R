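# Synthetic watershed generator: complete community brood tables, Steelhead
# life-cycle series, daily weather, and environmental covariates simulated
# from known parameters, so every pipeline stage is testable end to end and
# parameter recovery can be scored against stored truth.

#' Configuration for the synthetic watershed generator
#'
#' Defaults emulate a small rain-dominated coastal watershed monitored over
#' 1976-2015: five anadromous salmonid species with distinct age structures;
#' slow covariate trends (a logging ramp reaching a plateau, a logistic seal
#' recovery with an eightfold increase over the study years, a 2.4-fold rise
#' in North Pacific salmon abundance), a ~10-year ocean cycle, white-noise
#' climate; three-decade productivity regimes induced by a correlated
#' random-walk intercept (process SD 0.3); and nutrient-enrichment blocks in
#' 1983-1986 and 1997-2004. Missingness rates default to 10.5\% of adult
#' cohorts, 1.5\% of juvenile cohorts and 0.5\% of covariate years.
#'
#' @param years Brood years to simulate.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(years = 1976:2015, ...) {
  cfg <- list(
    years = as.integer(years),
    species = c("dolly_varden", "steelhead", "cutthroat", "coho", "pink"),
    age_profiles = list(
      dolly_varden = age_profile("dolly_varden",
        c(`1` = 0.4, `2` = 0.5, `3` = 0.1),
        c(`2` = 0.25, `3` = 0.5, `4` = 0.25)),
      steelhead = age_profile("steelhead",
        c(`1` = 0.2, `2` = 0.4, `3` = 0.3, `4` = 0.1),
        c(`2` = 0.5, `3` = 0.5)),
      cutthroat = age_profile("cutthroat",
        c(`2` = 0.25, `3` = 0.5, `4` = 0.25),
        c(`2` = 0.3, `3` = 0.5, `4` = 0.2)),
      coho = age_profile("coho", c(`1` = 1), c(`2` = 1)),
      pink = age_profile("pink", c(`0` = 1), c(`2` = 1))
    ),
    recruit_definition = c(dolly_varden = "smolt_outmigrants",
                           steelhead = "smolt_outmigrants",
                           cutthroat = "smolt_outmigrants",
                           coho = "smolt_outmigrants",
                           pink = "adults_t_plus_2"),
    # true stock-recruitment parameters
    ln_alpha0 = c(dolly_varden = 3.8, steelhead = 4.2, cutthroat = 3.6,
                  coho = 4.6, pink = 2.0),
    beta = c(dolly_varden = 0.0025, steelhead = 0.0015, cutthroat = 0.003,
             coho = 0.0006, pink = 0.00004),
    sigma_proc = 0.3, proc_cor = 0.5, proc_cor_pink = 0.1,
    sigma_obs = 0.4, obs_cor = 0.25,
    # generator-only demography closing the loop from recruits to spawners;
    # baseline productivity and marine survival are set so the deterministic
    # skeleton sits well above the demographic floor and regeneration is rare
    marine_survival = c(dolly_varden = 0.15, steelhead = 0.08,
                        cutthroat = 0.15, coho = 0.06, pink = 1.0),
    init_spawners = c(dolly_varden = 760, steelhead = 1100, cutthroat = 570,
                      coho = 3000, pink = 50000),
    spawner_floor = 0.5,
    # species -> covariate map and true coefficients (standardized scale)
    species_covariates = list(
      dolly_varden = c(logging = -0.2, winter_temp = 0.2, nutrients = -0.3),
      steelhead = c(logging = -0.5, pink_spawners = 0.3,
                    temp_post30 = 0.15, rain_post30 = -0.15),
      cutthroat = c(logging = -0.4, nutrients = -0.3, winter_rain = -0.2),
      coho = c(logging = -0.4, winter_temp = 0.3, summer_temp = -0.2),
      pink = c(ocean_interactions = -0.3, ocean_pca2 = -0.2, npgo = -0.2,
               summer_rain = 0.2)
    ),
    logging_window = 15,
    logging_ramp = list(start = 1966, peak_year = 1985, peak_area = 3.0,
                        plateau_end = 1998, late_area = 1.2, late_year = 2010),
    seal = list(fold = 8, rate = 0.25, midpoint = 1990, base = 1, noise_sd = 0),
    npsa = list(fold = 2.4, rate = 0.2, midpoint = 1988, base = 1, noise_sd = 0),
    ocean_cycle = list(period = 10, amplitude = 1, noise_sd = 0.2),
    nutrient_blocks = list(1983:1986, 1997:2004),
    weather = list(temp_mean = 8, temp_amp = 6, temp_sd = 2.5,
                   rain_meanlog = 1.2, rain_amplog = 0.9, rain_sdlog = 1),
    run_anchor_doy = 130,
    # Steelhead life-cycle truth
    steelhead_lc = list(
      m0 = -2.2, delta_m = c(ocean_interactions = -0.5, ocean_pca2 = -0.2),
      sigma_um = 0.1, sigma_m_obs = 0.3,
      S0 = 400, delta_S1 = 60, delta_S2 = 0.005, sigma_uS = 15, sigma_S = 30,
      T0 = 135, delta_TS = -6,
      delta_T = c(temp_pre14 = -2, rain_pre14 = 1),
      sigma_uT = 2, sigma_T = 5),
    missing = list(adults = 21 / 200, juveniles = 3 / 200,
                   covariates = 0.005, run_dates = 3 / 40),
    max_attempts = 25
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "generator_config")
}

# normalized logistic rising from exactly 0 at y0 to exactly 1 at y1
logistic_ramp <- function(years, rate, midpoint, y0, y1) {
  h <- plogis(rate * (years - midpoint))
  (h - plogis(rate * (y0 - midpoint))) /
    (plogis(rate * (y1 - midpoint)) - plogis(rate * (y0 - midpoint)))
}

# daily weather over a span of calendar years
generate_weather <- function(cfg, year_min, year_max) {
  dates <- seq(as.Date(paste0(year_min, "-01-01")),
               as.Date(paste0(year_max, "-12-31")), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  w <- cfg$weather
  seas_t <- w$temp_mean - w$temp_amp * cos(2 * pi * (doy - 15) / 365.25)
  temp <- seas_t + rnorm(length(dates), sd = w$temp_sd)
  mlog <- w$rain_meanlog + w$rain_amplog * cos(2 * pi * (doy - 15) / 365.25)
  rain <- exp(rnorm(length(dates), mlog, w$rain_sdlog))
  data.frame(date = dates, temp = temp, rain = rain)
}

# annual climate indices from daily weather; winter = Nov(y-1)..Feb(y),
# summer = Mar..Sep of y
annual_climate <- function(weather, years) {
  lt <- as.POSIXlt(weather$date)
  yr <- lt$year + 1900; mo <- lt$mon + 1
  wy <- ifelse(mo >= 11, yr + 1L, yr)  # winter assigned to ending year
  idx_w <- mo >= 11 | mo <= 2
  idx_s <- mo >= 3 & mo <= 9
  agg <- function(v, grp, keep, fun)
    vapply(years, function(y) {
      sel <- keep & grp == y
      if (!any(sel)) NA_real_ else fun(v[sel])
    }, numeric(1))
  list(
    winter_temp = cov_series("winter_temp", years,
                             agg(weather$temp, wy, idx_w, mean)),
    summer_temp = cov_series("summer_temp", years,
                             agg(weather$temp, yr, idx_s, mean)),
    winter_rain = cov_series("winter_rain", years,
                             agg(weather$rain, wy, idx_w, sum)),
    summer_rain = cov_series("summer_rain", years,
                             agg(weather$rain, yr, idx_s, sum))
  )
}

#' Generate the synthetic environmental covariates and daily weather
#'
#' Produces the annual covariate catalog (logged area, seal density with a
#' configurable fold increase over the study years, North Pacific salmon
#' abundance, a cyclical ocean index, climate indices derived from the daily
#' weather, and the nutrient-treatment indicator) plus the daily weather
#' series. Under zero configured noise the seal and NPSA series are
#' deterministic and their study-span fold increases hold exactly.
#'
#' @param config A [generator_config()].
#' @return A list with `catalog` (covariates with injected missingness),
#'   `catalog_complete` (no missingness; used as generation truth), and
#'   `weather` (daily data frame).
#' @export
generate_covariates <- function(config = generator_config()) {
  yrs <- config$years
  y0 <- min(yrs); y1 <- max(yrs)
  ann_years <- (y0 - config$logging_window - 11):(y1 + 8)
  lr <- config$logging_ramp
  logged <- approx(
    x = c(min(ann_years), lr$start, lr$peak_year, lr$plateau_end,
          lr$late_year, max(ann_years)),
    y = c(0, 0.2, lr$peak_area, lr$peak_area, lr$late_area, lr$late_area),
    xout = ann_years)$y
  seal_g <- logistic_ramp(ann_years, config$seal$rate, config$seal$midpoint,
                          y0, y1)
  seals <- config$seal$base * (1 + (config$seal$fold - 1) * seal_g)
  if (config$seal$noise_sd > 0)
    seals <- pmax(seals + rnorm(length(seals), sd = config$seal$noise_sd),
                  1e-6)
  npsa_g <- logistic_ramp(ann_years, config$npsa$rate, config$npsa$midpoint,
                          y0, y1)
  npsa <- config$npsa$base * (1 + (config$npsa$fold - 1) * npsa_g)
  if (config$npsa$noise_sd > 0)
    npsa <- pmax(npsa + rnorm(length(npsa), sd = config$npsa$noise_sd), 1e-6)
  oc <- config$ocean_cycle
  npgo <- oc$amplitude * cos(2 * pi * (ann_years - y0) / oc$period) +
    rnorm(length(ann_years), sd = oc$noise_sd)
  nutrients <- as.numeric(ann_years %in% unlist(config$nutrient_blocks))
  weather <- generate_weather(config, min(ann_years), max(ann_years))
  clim <- annual_climate(weather, ann_years)
  catalog <- c(list(
    logged_area = cov_series("logged_area", ann_years, logged),
    seals = cov_series("seals", ann_years, seals),
    npsa = cov_series("npsa", ann_years, npsa),
    npgo = cov_series("npgo", ann_years, npgo),
    nutrients = cov_series("nutrients", ann_years, nutrients)
  ), clim)
  gappy <- catalog
  if (config$missing$covariates > 0) {
    for (nm in c("winter_temp", "summer_temp", "winter_rain", "summer_rain",
                 "npgo")) {
      mis <- runif(length(ann_years)) < config$missing$covariates
      gappy[[nm]]$values[mis] <- NA_real_
      gappy[[nm]]$missing <- gappy[[nm]]$missing | mis
    }
  }
  list(catalog = gappy, catalog_complete = catalog, weather = weather)
}

# species-matched ocean principal components: cohort seal exposure and
# marine-phase NPSA, standardized then collapsed by PCA
ocean_pcs <- function(catalog, ages, brood_years, adult_only) {
  fw <- ages$freshwater_age_props; ma <- ages$marine_age_props
  sealexp <- vapply(brood_years, function(t) {
    s <- 0
    for (i in seq_along(fw)) for (j in seq_along(ma)) {
      out_y <- t + as.integer(names(fw)[i])
      sp_y <- out_y + as.integer(names(ma)[j])
      s <- s + fw[i] * ma[j] *
        seal_exposure(catalog$seals, out_y, sp_y, adult_only = adult_only)
    }
    s
  }, numeric(1))
  sl <- standardize(cov_series("seal_exposure", brood_years, sealexp))
  np <- standardize(lag_to_brood_year(catalog$npsa, ages, "marine",
                                      brood_years))
  np$name <- "npsa_marine"
  collapse_collinear_pca(sl, np)
}

# assemble one species' standardized brood-year design matrix from the
# covariate catalog (complete series required)
build_species_design <- function(config, catalog, species, weather = NULL,
                                 pink_spawners = NULL) {
  yrs <- config$years
  ages <- config$age_profiles[[species]]
  wanted <- names(config$species_covariates[[species]])
  cols <- list()
  pcs <- NULL
  for (nm in wanted) {
    cols[[nm]] <- switch(nm,
      logging = lag_to_brood_year(
        cumulative_logging(catalog$logged_area, config$logging_window),
        ages, "freshwater", yrs)$values,
      winter_temp = , summer_temp = , winter_rain = , summer_rain = ,
      nutrients = lag_to_brood_year(catalog[[nm]], ages, "freshwater",
                                    yrs)$values,
      pink_spawners = {
        if (is.null(pink_spawners)) stop("pink spawner series required")
        vapply(yrs, function(t) cov_at(pink_spawners, t), numeric(1))
      },
      npgo = lag_to_brood_year(catalog$npgo, ages, "marine", yrs)$values,
      ocean_interactions = , ocean_pca2 = {
        if (is.null(pcs))
          pcs <- ocean_pcs(catalog, ages, yrs,
                           adult_only = identical(species, "pink"))
        if (nm == "ocean_interactions") pcs$pc1$values else pcs$pc2$values
      },
      temp_post30 = , rain_post30 = {
        if (is.null(weather)) stop("daily weather required for window covariates")
        v <- if (nm == "temp_post30") "temp" else "rain"
        f <- if (nm == "temp_post30") mean else sum
        window_covariate(weather, yrs, config$run_anchor_doy, 30, v, f)$values
      },
      stop("unknown covariate '", nm, "' for ", species)
    )
  }
  vals <- do.call(cbind, cols)
  colnames(vals) <- wanted
  standardize(design_matrix(species, yrs, vals))
}

exch_cor <- function(d, rho) { m <- matrix(rho, d, d); diag(m) <- 1; m }

#' Generate the synthetic community brood tables
#'
#' Simulates latent intrinsic-productivity paths as correlated multivariate
#' random walks, propagates spawners by closed-loop demography (true Ricker
#' recruits routed to future spawning years through the fixed
#' proportions-at-age and a constant generator-only marine survival), and
#' draws observed recruitment productivity with correlated observation error.
#' If any spawner count falls below the configured floor the community is
#' regenerated (attempt count reported). Missing adult and juvenile cohorts
#' are injected completely at random at the configured rates.
#'
#' @param config A [generator_config()].
#' @param covariates Output of [generate_covariates()].
#' @return A list with `broods` (gappy [brood_table]s), `designs`
#'   (standardized, complete), and `truth` (latent paths, parameters, true
#'   spawners/recruits, attempt count).
#' @export
generate_community <- function(config = generator_config(),
                               covariates = generate_covariates(config)) {
  yrs <- config$years; T_ <- length(yrs); sp <- config$species
  d <- length(sp)
  cat_c <- covariates$catalog_complete
  # pass 1: pink design has no dependence on other species
  designs <- list()
  designs$pink <- build_species_design(config, cat_c, "pink",
                                       weather = covariates$weather)
  Sig_P <- exch_cor(d, config$proc_cor)
  Sig_P[d, ] <- Sig_P[, d] <- config$proc_cor_pink
  diag(Sig_P) <- 1
  Sig_P <- Sig_P * config$sigma_proc^2
  Sig_O <- exch_cor(d, config$obs_cor) * config$sigma_obs^2
  L_P <- if (config$sigma_proc > 0) t(chol(Sig_P)) else matrix(0, d, d)
  L_O <- if (config$sigma_obs > 0) t(chol(Sig_O)) else matrix(0, d, d)

  for (attempt in seq_len(config$max_attempts)) {
    # latent productivity paths
    A <- matrix(0, T_, d, dimnames = list(yrs, sp))
    A[1, ] <- config$ln_alpha0[sp]
    for (t in 2:T_) A[t, ] <- A[t - 1, ] + drop(L_P %*% rnorm(d))
    simulate_species <- function(species, X) {
      ages <- config$age_profiles[[species]]
      fw <- ages$freshwater_age_props; ma <- ages$marine_age_props
      beta <- config$beta[[species]]; smar <- config$marine_survival[[species]]
      a <- A[, species]
      R_pre <- config$init_spawners[[species]] / smar
      Rstar <- setNames(rep(R_pre, T_), yrs)
      S <- setNames(numeric(T_), yrs)
      for (ti in seq_len(T_)) {
        t <- yrs[ti]
        inflow <- 0
        for (i in seq_along(fw)) for (j in seq_along(ma)) {
          b <- t - as.integer(names(fw)[i]) - as.integer(names(ma)[j])
          rb <- if (b < yrs[1]) R_pre else Rstar[as.character(b)]
          inflow <- inflow + fw[i] * ma[j] * smar * rb
        }
        S[ti] <- inflow
        mu <- a[ti] - beta * S[ti] + sum(X[ti, ] *
          config$species_covariates[[species]])
        Rstar[ti] <- S[ti] * exp(mu)
      }
      list(S = S, Rstar = Rstar)
    }
    pinksim <- simulate_species("pink", designs$pink$values)
    pink_sp <- cov_series("pink_spawners", yrs, pinksim$S)
    for (s in setdiff(sp, "pink"))
      designs[[s]] <- build_species_design(config, cat_c, s,
                                           weather = covariates$weather,
                                           pink_spawners = pink_sp)
    sims <- list(pink = pinksim)
    for (s in setdiff(sp, "pink"))
      sims[[s]] <- simulate_species(s, designs[[s]]$values)
    Smat <- vapply(sp, function(s) sims[[s]]$S, numeric(T_))
    if (min(Smat) >= config$spawner_floor) break
    if (attempt == config$max_attempts)
      stop("community regeneration exceeded max_attempts")
    warning("spawners fell below floor; regenerating community (attempt ",
            attempt, ")")
  }
  # observed productivity with correlated observation error
  MU <- vapply(seq_len(d), function(j) {
    s <- sp[j]
    A[, s] - config$beta[[s]] * sims[[s]]$S +
      drop(designs[[s]]$values %*% config$species_covariates[[s]])
  }, numeric(T_))
  V <- t(L_O %*% matrix(rnorm(T_ * d), d, T_))
  Yobs <- MU + V
  Rmat <- vapply(seq_len(d), function(j) sims[[sp[j]]]$S * exp(Yobs[, j]),
                 numeric(T_))
  broods <- list()
  for (j in seq_len(d)) {
    s <- sp[j]
    spawn <- Smat[, j]; rec <- Rmat[, j]
    spawn[runif(T_) < config$missing$adults] <- NA_real_
    rec[runif(T_) < config$missing$juveniles] <- NA_real_
    broods[[s]] <- brood_table(s, yrs, spawn, rec,
                               config$recruit_definition[[s]])
  }
  designs <- designs[sp]
  list(broods = broods, designs = designs,
       truth = list(ln_alpha = A, beta = config$beta[sp],
                    delta = config$species_covariates[sp],
                    Sigma_P = Sig_P, Sigma_O = Sig_O,
                    spawners = Smat, recruits = Rmat,
                    recruits_true = vapply(sp, function(s) sims[[s]]$Rstar,
                                           numeric(T_)),
                    attempts = attempt))
}

#' Generate the synthetic Steelhead life-cycle series
#'
#' Takes the community's true Steelhead smolt production, routes cohorts to
#' their out-migration years, and simulates the linked marine-survival, adult
#' return, and run-timing equations forward with random-walk intercepts. The
#' run-timing and smolt-production climate covariates are computed from the
#' daily weather with 14-day-before and 30-day-after windows, so the
#' windowing code is exercised end to end. The first cohort's survival
#' observation is withheld (as in fence monitoring that starts with the first
#' adult return) and further missing adults/run dates are injected at random.
#'
#' @param config A [generator_config()].
#' @param community Output of [generate_community()].
#' @param covariates Output of [generate_covariates()].
#' @return A list with `series` (a [steelhead_series]), `design_m`, `design_t`
#'   (standardized), and `truth`.
#' @export
generate_steelhead <- function(config, community, covariates) {
  yrs <- config$years; T_ <- length(yrs)
  lc <- config$steelhead_lc
  cat_c <- covariates$catalog_complete
  ages <- config$age_profiles$steelhead
  fw <- ages$freshwater_age_props
  Rstar <- community$truth$recruits_true[, "steelhead"]
  R_pre <- config$init_spawners[["steelhead"]] /
    config$marine_survival[["steelhead"]]
  F_ <- vapply(yrs, function(y) {
    s <- 0
    for (i in seq_along(fw)) {
      b <- y - as.integer(names(fw)[i])
      rb <- if (b < yrs[1]) R_pre else Rstar[as.character(b)]
      s <- s + fw[i] * rb
    }
    s
  }, numeric(1))
  pcs <- ocean_pcs(cat_c, ages, yrs, adult_only = FALSE)
  Xm <- cbind(ocean_interactions = pcs$pc1$values,
              ocean_pca2 = pcs$pc2$values)
  design_m <- design_matrix("steelhead", yrs, Xm)
  design_m <- standardize(design_m)
  m0 <- random_walk_path(lc$m0, rnorm(T_ - 1, sd = lc$sigma_um))
  m_t <- vapply(seq_len(T_), function(t)
    marine_survival(m0[t], lc$delta_m, design_m$values[t, ]), numeric(1))
  l_obs <- m_t + rnorm(T_, sd = lc$sigma_m_obs)
  S0 <- random_walk_path(lc$S0, rnorm(T_ - 1, sd = lc$sigma_uS))
  S_t <- vapply(seq_len(T_), function(t)
    adult_returns(S0[t], lc$delta_S1, m_t[t], lc$delta_S2, F_[t]), numeric(1)) +
    rnorm(T_, sd = lc$sigma_S)
  n_floored <- sum(S_t < config$spawner_floor)
  S_t <- pmax(S_t, config$spawner_floor)
  T0 <- random_walk_path(lc$T0, rnorm(T_ - 1, sd = lc$sigma_uT))
  T_prov <- T0 + lc$delta_TS * log(S_t)
  anchor <- pmin(pmax(round(T_prov), 40), 320)
  xt_temp <- window_covariate(covariates$weather, yrs, anchor, -14, "temp", mean)
  xt_rain <- window_covariate(covariates$weather, yrs, anchor, -14, "rain", sum)
  design_t <- standardize(design_matrix("steelhead", yrs,
    cbind(temp_pre14 = xt_temp$values, rain_pre14 = xt_rain$values)))
  T_t <- T_prov + drop(design_t$values %*% lc$delta_T) +
    rnorm(T_, sd = lc$sigma_T)
  # observation missingness
  S_obs <- S_t; l_o <- l_obs; T_o <- T_t
  mis_S <- runif(T_) < config$missing$adults
  S_obs[mis_S] <- NA_real_; l_o[mis_S] <- NA_real_
  l_o[1] <- NA_real_   # first cohort's survival has no observed antecedent
  T_o[runif(T_) < config$missing$run_dates | mis_S] <- NA_real_
  series <- steelhead_series(yrs, F_, S_obs, T_o, logit_survival = l_o)
  list(series = series, design_m = design_m, design_t = design_t,
       truth = list(m0 = m0, S0 = S0, T0 = T0, m = m_t, adults = S_t,
                    run_date = T_t, smolts = F_, lc = lc,
                    n_floored = n_floored))
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generate_covariates()], [generate_community()], and
#' [generate_steelhead()] under one seed: the full set of inputs the analysis
#' pipeline consumes, plus the generating truth for recovery tests.
#'
#' @param config A [generator_config()].
#' @param seed Integer RNG seed.
#' @return A list: `covariates` (gappy catalog), `covariates_complete`,
#'   `weather`, `broods`, `designs`, `steelhead`, `truth`, `config`.
#' @export
generate_dataset <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cv <- generate_covariates(config)
  cm <- generate_community(config, cv)
  sh <- generate_steelhead(config, cm, cv)
  list(covariates = cv$catalog, covariates_complete = cv$catalog_complete,
       weather = cv$weather, broods = cm$broods, designs = cm$designs,
       steelhead = sh[c("series", "design_m", "design_t")],
       truth = list(community = cm$truth, steelhead = sh$truth),
       config = config)
}
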