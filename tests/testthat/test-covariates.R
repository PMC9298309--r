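# Covariate construction: cumulative logging windows, brood-year lagging,
# seal exposure, PCA collapsing, standardization, VIF screening.

test_that("cumulative logging sums the trailing window", {
  x <- cov_series("logged_area", 1990:1992, c(2, 3, 5))
  out <- cumulative_logging(x, 2)
  expect_equal(out$years, 1991:1992)
  expect_equal(out$values, c(5, 8))

  const <- cov_series("logged_area", 1960:1999, rep(1.5, 40))
  out15 <- cumulative_logging(const, 15)
  expect_true(all(abs(out15$values - 22.5) < 1e-12))
  expect_equal(out15$years, 1974:1999)

  expect_equal(cumulative_logging(x, 1)$values, x$values)
})

test_that("cumulative logging rejects bad input and never zero-fills", {
  expect_error(cov_series("a", integer(0), numeric(0)), "empty")
  neg <- cov_series("a", 1990:1992, c(1, -1, 2))
  expect_error(cumulative_logging(neg, 2), "negative")
  short <- cov_series("a", 1990:1995, rep(1, 6))
  expect_error(cumulative_logging(short, 15), "pre-series")
  expect_error(cumulative_logging(short, 0), "window_years")
})

test_that("cumulative logging is non-decreasing on monotone input", {
  x <- cov_series("a", 1960:2000, seq(0, 4, length.out = 41))
  out <- cumulative_logging(x, 15)
  expect_true(all(diff(out$values) >= -1e-12))
})

test_that("brood-year lagging follows the rearing-span convention", {
  cv <- cov_series("temp", 1970:1990, 1970:1990)
  # age-1 cohort rears only in its brood year: identity
  ap1 <- age_profile("s", c(`1` = 1), c(`2` = 1))
  expect_equal(lag_to_brood_year(cv, ap1, "freshwater", 1975:1980)$values,
               1975:1980 + 0)
  # age-3 cohort rears in t..t+2
  ap3 <- age_profile("s", c(`3` = 1), c(`2` = 1))
  expect_equal(lag_to_brood_year(cv, ap3, "freshwater", 1975)$values, 1976)
  # fry migrant (age 0) experiences only year t
  ap0 <- age_profile("s", c(`0` = 1), c(`2` = 1))
  expect_equal(lag_to_brood_year(cv, ap0, "freshwater", 1980)$values, 1980)
  # mixed ages: explicit weighted-sum oracle
  ap <- age_profile("s", c(`1` = 0.5, `2` = 0.5), c(`2` = 1))
  got <- lag_to_brood_year(cv, ap, "freshwater", 1975)$values
  expect_equal(got, 0.5 * 1975 + 0.5 * mean(c(1975, 1976)))
  # constant covariate returns the constant for any age profile
  cc <- cov_series("c", 1960:2000, rep(7, 41))
  apx <- age_profile("s", c(`1` = .2, `2` = .5, `3` = .3),
                     c(`2` = .5, `3` = .5))
  expect_true(all(abs(lag_to_brood_year(cc, apx, "freshwater",
                                        1975:1985)$values - 7) < 1e-12))
  expect_true(all(abs(lag_to_brood_year(cc, apx, "marine",
                                        1975:1985)$values - 7) < 1e-12))
})

test_that("marine lagging spans out-migration through return", {
  cv <- cov_series("npsa", 1970:1995, 1970:1995)
  ap <- age_profile("s", c(`2` = 1), c(`3` = 1))
  # brood 1980: at sea 1982..1985
  expect_equal(lag_to_brood_year(cv, ap, "marine", 1980)$values,
               mean(1982:1985))
})

test_that("lagging is linear in the covariate and errors name missing years", {
  set.seed(1)
  ap <- age_profile("s", c(`1` = .4, `2` = .6), c(`2` = 1))
  y <- 1970:1995
  c1 <- cov_series("a", y, rnorm(26))
  c2 <- cov_series("b", y, rnorm(26))
  cs <- cov_series("ab", y, c1$values + c2$values)
  by <- 1975:1990
  expect_equal(lag_to_brood_year(cs, ap, "freshwater", by)$values,
               lag_to_brood_year(c1, ap, "freshwater", by)$values +
                 lag_to_brood_year(c2, ap, "freshwater", by)$values)
  expect_error(lag_to_brood_year(c1, ap, "freshwater", 1995), "1996")
})

test_that("seal exposure sums out-migration and spawning years", {
  s <- cov_series("seals", 2000:2003, c(1, 2, 3, 4))
  expect_identical(seal_exposure(s, 2000, 2003), 5)
  expect_identical(seal_exposure(s, 2000, 2003, adult_only = TRUE), 4)
  z <- cov_series("seals", 2000:2003, rep(0, 4))
  expect_identical(seal_exposure(z, 2000, 2003), 0)
  expect_error(seal_exposure(s, 1999, 2003), "1999")
})

test_that("PCA collapse conserves variance with uncorrelated scores", {
  yrs <- 1976:2015
  set.seed(2)
  a <- standardize(cov_series("seals", yrs, cumsum(rnorm(40))))
  b0 <- 0.7 * a$values + rnorm(40, sd = 0.5)
  b <- standardize(cov_series("npsa", yrs, b0))
  pc <- collapse_collinear_pca(a, b)
  expect_lt(abs(var(pc$pc1$values) + var(pc$pc2$values) -
                  var(a$values) - var(b$values)), 1e-8)
  expect_lt(abs(cor(pc$pc1$values, pc$pc2$values)), 1e-8)
  # independent oracle: prcomp scores match up to sign
  pr <- prcomp(cbind(a$values, b$values), center = TRUE, scale. = FALSE)
  expect_lt(min(sum((pc$pc1$values - pr$x[, 1])^2),
                sum((pc$pc1$values + pr$x[, 1])^2)), 1e-16)
  # sign convention: pc1 positive on first input, pc2 negative on second
  expect_gt(pc$loadings[1, "pc1"], 0)
  expect_gt(pc$loadings[1, "pc2"], 0)
  expect_lt(pc$loadings[2, "pc2"], 0)
})

test_that("PCA collapse handles perfectly collinear pairs", {
  yrs <- 1976:2015
  set.seed(3)
  a <- standardize(cov_series("a", yrs, rnorm(40)))
  b <- a; b$name <- "b"
  pc <- collapse_collinear_pca(a, b)
  expect_gt(pc$var_explained[1], 1 - 1e-10)
  expect_true(all(abs(pc$pc2$values) < 1e-6))
  bneg <- a; bneg$name <- "b"; bneg$values <- -a$values
  pcn <- collapse_collinear_pca(a, bneg)
  expect_gt(pcn$var_explained[1], 1 - 1e-10)
  cshort <- cov_series("c", 1976:2000, rnorm(25))
  expect_error(collapse_collinear_pca(a, cshort), "same years")
})

test_that("standardization uses the population SD and is invertible", {
  dm <- design_matrix("sp", 1:3, cbind(x = c(1, 2, 3)))
  st <- standardize(dm)
  expect_equal(st$values[, "x"], c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(st$standardization$sd[["x"]], sqrt(2 / 3))
  # idempotent
  st2 <- standardize(st)
  expect_lt(max(abs(st2$values - st$values)), 1e-8)
  # invertible
  back <- unstandardize(st)
  expect_equal(back$values, dm$values, tolerance = 1e-12)
  # zero-variance column named in the error
  dmc <- design_matrix("sp", 1:3, cbind(flat = c(2, 2, 2)))
  expect_error(standardize(dmc), "flat")
})

test_that("VIF screening matches an independent oracle and flags collinearity", {
  set.seed(4)
  n <- 60
  X <- unclass(poly(seq_len(n), 3))  # exactly orthogonal, mean-zero columns
  colnames(X) <- c("a", "b", "c")
  v <- vif_screen(design_matrix("sp", seq_len(n), X))
  expect_true(all(abs(v$vif - 1) < 1e-8))
  expect_false(any(v$flag))

  # correlated design: oracle via inverse correlation matrix
  z <- rnorm(n)
  Xc <- cbind(a = z + rnorm(n), b = z + rnorm(n), c = rnorm(n))
  v2 <- vif_screen(Xc)
  oracle <- diag(solve(cor(Xc)))
  expect_equal(v2$vif, unname(oracle), tolerance = 1e-8)

  # duplicated column reported as infinite and flagged
  Xd <- cbind(a = z, b = z, c = rnorm(n))
  v3 <- vif_screen(Xd)
  expect_true(all(!is.finite(v3$vif[1:2])))
  expect_true(all(v3$flag[1:2]))
  expect_error(vif_screen(Xd[, 1, drop = FALSE]), "two columns")
})
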