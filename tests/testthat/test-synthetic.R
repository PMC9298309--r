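# Synthetic watershed generator: determinism, configured trends, validity of
# the generated bundles, and truth recovery of the headline mechanisms.

test_that("generation is reproducible under a fixed seed", {
  d1 <- suppressWarnings(generate_dataset(seed = 70))
  d2 <- suppressWarnings(generate_dataset(seed = 70))
  expect_identical(d1$broods, d2$broods)
  expect_identical(d1$steelhead$series, d2$steelhead$series)
  expect_identical(d1$truth, d2$truth)
})

test_that("configured seal and NPSA fold increases hold exactly", {
  cfg <- generator_config()
  cv <- generate_covariates(cfg)
  seals <- cv$catalog_complete$seals
  i0 <- match(min(cfg$years), seals$years)
  i1 <- match(max(cfg$years), seals$years)
  expect_lt(abs(seals$values[i1] / seals$values[i0] - 8), 1e-9)
  npsa <- cv$catalog_complete$npsa
  expect_lt(abs(npsa$values[i1] / npsa$values[i0] - 2.4), 1e-9)
  # other configured folds propagate
  cfg2 <- generator_config(seal = list(fold = 3, rate = 0.25, midpoint = 1990,
                                       base = 2, noise_sd = 0))
  cv2 <- generate_covariates(cfg2)
  s2 <- cv2$catalog_complete$seals
  expect_lt(abs(s2$values[i1] / s2$values[i0] - 3), 1e-9)
})

test_that("zero-noise covariate curves are deterministic", {
  cfg <- generator_config()
  set.seed(1); a <- generate_covariates(cfg)$catalog_complete
  set.seed(2); b <- generate_covariates(cfg)$catalog_complete
  expect_identical(a$seals$values, b$seals$values)
  expect_identical(a$npsa$values, b$npsa$values)
  expect_identical(a$logged_area$values, b$logged_area$values)
  expect_false(identical(a$npgo$values, b$npgo$values))  # has noise
})

test_that("the nutrient indicator marks the configured treatment blocks", {
  cv <- generate_covariates(generator_config())
  nut <- cv$catalog_complete$nutrients
  on_years <- nut$years[nut$values == 1]
  expect_setequal(on_years, c(1983:1986, 1997:2004))
})

test_that("generated datasets pass the pipeline's own input validation", {
  ds <- suppressWarnings(generate_dataset(seed = 71))
  for (bt in ds$broods) {
    expect_s3_class(bt, "brood_table")
    expect_true(all(bt$spawners >= 0, na.rm = TRUE))
    expect_true(all(bt$recruits >= 0, na.rm = TRUE))
    expect_true(all(is.finite(bt$log_rps[!bt$missing])))
  }
  for (dm in ds$designs) {
    expect_lt(max(abs(colMeans(dm$values))), 1e-8)
    psd <- apply(dm$values, 2, function(v) sqrt(mean((v - mean(v))^2)))
    expect_lt(max(abs(psd - 1)), 1e-8)
    expect_false(is.null(dm$standardization))
    v <- vif_screen(dm)
    expect_true(all(is.finite(v$vif)))
  }
  # covariate missingness is sparse, as configured
  mis_frac <- mean(unlist(lapply(ds$covariates, `[[`, "missing")))
  expect_lt(mis_frac, 0.02)
  # alignment with the steelhead bundle
  expect_identical(ds$steelhead$series$years, ds$broods$steelhead$brood_years)
})

test_that("missingness injection matches the configured rates", {
  set.seed(72)
  tot_sp <- 0; tot_re <- 0; n <- 0
  for (r in 1:8) {
    ds <- suppressWarnings(generate_dataset(seed = 7200 + r))
    tot_sp <- tot_sp + sum(vapply(ds$broods, function(b)
      sum(is.na(b$spawners)), numeric(1)))
    tot_re <- tot_re + sum(vapply(ds$broods, function(b)
      sum(is.na(b$recruits)), numeric(1)))
    n <- n + 200
  }
  expect_gt(tot_sp / n, 0.05); expect_lt(tot_sp / n, 0.17)
  expect_lt(tot_re / n, 0.05)
})

test_that("process correlation propagates into realized productivity paths", {
  cfg <- generator_config(years = 1976:2175, proc_cor = 0.9,
                          spawner_floor = 0)
  cv <- suppressWarnings(generate_covariates(cfg))
  cm <- suppressWarnings(generate_community(cfg, cv))
  A <- cm$truth$ln_alpha
  r <- cor(diff(A[, "dolly_varden"]), diff(A[, "steelhead"]))
  expect_lt(abs(r - 0.9), 0.08)
})

test_that("a stationary community is recovered by the stationary model", {
  cfg <- generator_config(sigma_proc = 1e-12)
  ds <- suppressWarnings(generate_dataset(cfg, seed = 73))
  # flat latent paths by construction
  expect_lt(max(abs(apply(ds$truth$community$ln_alpha, 2, function(v)
    diff(range(v))))), 1e-9)
  fit <- fit_community(ds$broods, ds$designs, variant = "stationary",
                       seed = 74, iter = 800)
  q <- apply(fit$draws$beta, 2, quantile, c(0.025, 0.975))
  covered <- unlist(ds$truth$community$beta) >= q[1, ] &
    unlist(ds$truth$community$beta) <= q[2, ]
  expect_gte(sum(covered), 4)
})

test_that("zero-noise steelhead dynamics are a deterministic map of smolts", {
  cfg <- generator_config()
  cfg$steelhead_lc$sigma_m_obs <- 0
  cfg$steelhead_lc$sigma_um <- 1e-12
  cfg$steelhead_lc$sigma_uS <- 1e-12
  cfg$steelhead_lc$sigma_S <- 0
  cfg$missing$adults <- 0; cfg$missing$run_dates <- 0
  set.seed(75)
  cv <- generate_covariates(cfg)
  cm <- suppressWarnings(generate_community(cfg, cv))
  sh <- generate_steelhead(cfg, cm, cv)
  lc <- cfg$steelhead_lc
  m <- lc$m0 + drop(sh$design_m$values %*% lc$delta_m)
  want <- lc$S0 + lc$delta_S1 * m + lc$delta_S2 * sh$truth$smolts
  expect_equal(sh$truth$adults, pmax(want, cfg$spawner_floor),
               tolerance = 1e-6)
})

test_that("headline mechanisms are recovered with high sign certainty", {
  # strong logging and pink-subsidy effects on Steelhead productivity, and a
  # strong ocean-interaction effect on marine survival
  wins <- c(logging = 0, pink = 0, ocean = 0)
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    cfg <- generator_config()
    cfg$species_covariates$steelhead[c("logging", "pink_spawners")] <- c(-1, 1)
    cfg$steelhead_lc$delta_m["ocean_interactions"] <- -1
    ds <- suppressWarnings(generate_dataset(cfg, seed = 7600 + r))
    fit <- fit_community(ds$broods, ds$designs, seed = 7700 + r, iter = 1000)
    sp_log <- sign_probability(fit$draws$delta[, "steelhead:logging"])
    sp_pink <- sign_probability(fit$draws$delta[, "steelhead:pink_spawners"])
    fs <- fit_steelhead(ds$steelhead$series, ds$steelhead$design_m,
                        ds$steelhead$design_t, seed = 7800 + r, iter = 800)
    sp_oc <- sign_probability(fs$draws$delta_m[, "ocean_interactions"])
    wins["logging"] <- wins["logging"] + (sp_log["negative"] > 0.9)
    wins["pink"] <- wins["pink"] + (sp_pink["positive"] > 0.9)
    wins["ocean"] <- wins["ocean"] + (sp_oc["negative"] > 0.9)
  }
  expect_gte(wins[["logging"]], 0.8 * n_rep)
  expect_gte(wins[["pink"]], 0.8 * n_rep)
  expect_gte(wins[["ocean"]], 0.8 * n_rep)
})
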