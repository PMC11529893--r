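# Regime classification, preseason selection, sensitivity estimation and
# asymmetry tests.

test_that("planted trends classify as warming/cooling; flat stays none", {
  cfg_w <- tiny_cfg(regime = "warming", temp_noise_sd = 0.5, seed = 2)
  expect_identical(classify_regime(generate_climate(cfg_w, 1))$regime, "warming")
  cfg_c <- tiny_cfg(regime = "cooling", temp_noise_sd = 0.5, seed = 2)
  expect_identical(classify_regime(generate_climate(cfg_c, 1))$regime, "cooling")
  cl0 <- make_climate(c(2000, 2019), tmean = 10)
  expect_identical(classify_regime(cl0)$regime, "none")
})

test_that("shift classification needs two significant opposite regimes", {
  cfg <- tiny_cfg(regime = "shift", years = c(1989L, 2018L),
                  temp_noise_sd = 0.5, trend_per_year = 0.15, seed = 5)
  cl <- generate_climate(cfg, 1)  # odd site: warm then cool
  expect_identical(classify_shift(cl, c(1989, 2003), c(2004, 2018)),
                   "warm_to_cool")
  cl2 <- generate_climate(cfg, 2)  # even site: cool then warm
  expect_identical(classify_shift(cl2, c(1989, 2003), c(2004, 2018)),
                   "cool_to_warm")
  cfg_w <- tiny_cfg(regime = "warming", years = c(1989L, 2018L),
                    temp_noise_sd = 0.5, trend_per_year = 0.15, seed = 5)
  cl3 <- generate_climate(cfg_w, 1)  # monotone warming: no shift
  expect_identical(classify_shift(cl3, c(1989, 2003), c(2004, 2018)), "none")
})

test_that("moving windows recover planted warm-then-cool structure", {
  cfg <- tiny_cfg(regime = "shift", years = c(1989L, 2018L),
                  temp_noise_sd = 0.4, trend_per_year = 0.15, seed = 3)
  cl <- generate_climate(cfg, 1)
  lsd_df <- data.frame(year = 1989:2018, lsd = 285)
  mw <- moving_window_regimes(cl, lsd_df, window = 15L)
  expect_identical(nrow(mw), 16L)
  expect_identical(mw$regime[1], "warming")
  expect_identical(mw$regime[nrow(mw)], "cooling")
  expect_true(all(mw$n_lsd == 15))
  # window equal to the series length -> exactly one window
  mw1 <- moving_window_regimes(cl, lsd_df, window = 30L)
  expect_identical(nrow(mw1), 1L)
  expect_error(moving_window_regimes(cl, lsd_df[1:10, ], window = 15L),
               "shorter")
  # constant temperature -> all windows none
  cl0 <- make_climate(c(1989, 2018), tmean = 10)
  mw0 <- moving_window_regimes(cl0, lsd_df, window = 15L)
  expect_true(all(mw0$regime == "none"))
})

test_that("optimal preseason recovers the planted driving window", {
  cfg <- tiny_cfg(trend_per_year = 0, noise_sd_lsd = 2,
                  planted_sens_cool = 7.5, preseason_len_true = 40L,
                  years = c(1989L, 2018L), seed = 12)
  cl <- generate_climate(cfg, 1)
  tr <- generate_lsd_truth(cfg, cl)
  pw <- optimal_preseason(data.frame(year = tr$year, lsd = tr$lsd_true), cl)
  expect_true(abs(pw$length - 40) <= 8)
  expect_lt(pw$p, 0.05)
})

test_that("optimal preseason is invariant to constant shifts of LSD and temperature", {
  cfg <- tiny_cfg(trend_per_year = 0, noise_sd_lsd = 2,
                  planted_sens_cool = 7.5, years = c(1989L, 2018L), seed = 12)
  cl <- generate_climate(cfg, 1)
  tr <- generate_lsd_truth(cfg, cl)
  lsd_df <- data.frame(year = tr$year, lsd = tr$lsd_true)
  pw <- optimal_preseason(lsd_df, cl, anchor = 285L)
  # constant temperature offset
  cl2 <- cl; cl2$tmean <- cl2$tmean + 5
  pw2 <- optimal_preseason(lsd_df, cl2, anchor = 285L)
  expect_identical(pw2$length, pw$length)
  expect_equal(pw2$r, pw$r, tolerance = 1e-10)
  # constant senescence-date offset (window end held fixed)
  lsd_df3 <- lsd_df; lsd_df3$lsd <- lsd_df3$lsd + 3
  pw3 <- optimal_preseason(lsd_df3, cl, anchor = 285L)
  expect_identical(pw3$length, pw$length)
  expect_equal(pw3$r, pw$r, tolerance = 1e-10)
  expect_error(optimal_preseason(lsd_df[1:4, ], cl), "at least 5")
})

test_that("ridge solution matches the closed-form normal equations", {
  set.seed(42)
  for (i in 1:10) {
    n <- 25
    covars <- data.frame(temp = rnorm(n), precip = rnorm(n), rad = rnorm(n))
    y <- 2 * covars$temp - covars$precip + rnorm(n)
    lambda <- runif(1, 0.01, 5)
    res <- ridge_sensitivity(y, covars, lambda = lambda, n_boot = 10,
                             boot_seed = 1)
    # independent oracle: beta = (X'X + lambda I)^-1 X'y on the same
    # centered min-max-scaled anomalies
    s01 <- function(v) { a <- v - mean(v); (a - min(a)) / (max(a) - min(a)) }
    X <- scale(cbind(temp = s01(covars$temp), precip = s01(covars$precip),
                     rad = s01(covars$rad)), center = TRUE, scale = FALSE)
    ys <- s01(y); ys <- ys - mean(ys)
    beta <- solve(crossprod(X) + lambda * diag(3), crossprod(X, ys))
    expect_lt(max(abs(res$coefficients - drop(beta))), 1e-10)
  }
})

test_that("ridge limits: identity response at lambda -> 0, shrinkage at large lambda", {
  set.seed(3)
  covars <- data.frame(temp = rnorm(30), precip = rnorm(30), rad = rnorm(30))
  res0 <- ridge_sensitivity(covars$temp, covars, lambda = 1e-10, n_boot = 10,
                            boot_seed = 1)
  expect_equal(res0$slope, 1, tolerance = 1e-6)
  res_inf <- ridge_sensitivity(covars$temp, covars, lambda = 1e8, n_boot = 10,
                               boot_seed = 1)
  expect_lt(abs(res_inf$slope), 1e-4)
  # lambda = 0 equals OLS on the same scaled design
  res_ols <- ridge_sensitivity(rnorm(30) + covars$temp, covars, lambda = 0,
                               n_boot = 10, boot_seed = 1)
  expect_true(is.finite(res_ols$slope))
})

test_that("zero-variance covariate is dropped with a warning", {
  set.seed(4)
  covars <- data.frame(temp = rnorm(20), precip = rep(1, 20), rad = rnorm(20))
  expect_warning(res <- ridge_sensitivity(covars$temp + rnorm(20, 0, 0.1),
                                          covars, lambda = 0.1, n_boot = 10,
                                          boot_seed = 1),
                 "precip")
  expect_false("precip" %in% names(res$coefficients))
})

test_that("MLR sensitivity recovers a planted slope and flags rank deficiency", {
  set.seed(10)
  n <- 30
  covars <- data.frame(temp = rnorm(n), precip = rnorm(n), rad = rnorm(n))
  y <- 300 + 7.5 * covars$temp + rnorm(n, 0, 1)
  res <- mlr_sensitivity(y, covars)
  expect_true(res$ci[1] < 7.5 && 7.5 < res$ci[2])
  expect_lt(res$p, 0.001)
  covars$rad <- covars$temp  # exact collinearity
  expect_error(mlr_sensitivity(y, covars), "rank-deficient")
  expect_error(mlr_sensitivity(1, data.frame(temp = 1, precip = 1, rad = 1)),
               "at least")
})

test_that("group t-test detects planted asymmetry and respects group sizes", {
  set.seed(5)
  slopes <- c(rnorm(100, 7.5, 1), rnorm(100, 3.3, 1))
  regime <- rep(c("warming", "cooling"), each = 100)
  at <- group_sensitivities(slopes, regime)
  expect_lt(at$p, 1e-10)
  expect_gt(at$means["warming"], at$means["cooling"])
  expect_error(group_sensitivities(c(1, 2, 3), c("warming", "cooling", "cooling")),
               "at least 2")
})

test_that("ANCOVA slope comparison tests the interaction term", {
  set.seed(6)
  x <- runif(120, 0, 50)
  g <- rep(c("warming", "cooling"), each = 60)
  y <- ifelse(g == "warming", 0.6, 0.3) * x + rnorm(120, 0, 1)
  at <- compare_slopes_ancova(x, y, g)
  expect_lt(at$p, 1e-6)
  expect_equal(unname(diff(at$slopes)), 0.3, tolerance = 0.1)
  expect_error(compare_slopes_ancova(x[1:60], y[1:60], g[1:60]), "two groups")
})

test_that("null slope difference rejects near the nominal rate", {
  set.seed(8)
  rej <- mean(vapply(1:400, function(i) {
    x <- runif(60, 0, 50)
    g <- rep(c("warming", "cooling"), each = 30)
    y <- 0.5 * x + rnorm(60)
    compare_slopes_ancova(x, y, g)$p < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("mixed model recovers a planted regime offset over biome intercepts", {
  set.seed(9)
  n_per <- 60
  biome <- rep(c("ENF", "DBF", "MF"), length.out = 2 * n_per)
  regime <- rep(c("warming", "cooling"), each = n_per)
  b_off <- c(ENF = 0.2, DBF = -0.4, MF = 0.3)
  vals <- 2 + (regime == "warming") * 1.0 + b_off[biome] + rnorm(2 * n_per, 0, 0.4)
  at <- mixed_compare(vals, regime, biome)
  expect_lt(at$p, 1e-6)
  expect_equal(at$contrast, 1.0, tolerance = 0.35)
  expect_false(at$fallback)
  # single biome degenerates to the OLS contrast
  at1 <- mixed_compare(vals, regime, rep("ENF", 2 * n_per))
  expect_true(at1$fallback)
})

test_that("random-slope model detects regime-specific slopes over locations", {
  set.seed(11)
  n_cell <- 40
  lat <- runif(n_cell, 45, 55); lon <- runif(n_cell, 0, 20)
  regime <- rep(c("warming", "cooling"), each = n_cell / 2)
  rows <- do.call(rbind, lapply(seq_len(n_cell), function(i) {
    x <- runif(12, 0, 40)
    slope <- ifelse(regime[i] == "warming", 0.6, 0.3) + rnorm(1, 0, 0.03)
    data.frame(x = x, y = slope * x + rnorm(12, 0, 0.8), regime = regime[i],
               lat = lat[i], lon = lon[i])
  }))
  at <- random_slope_compare(rows$x, rows$y, rows$regime, rows$lat, rows$lon)
  expect_identical(at$method, "random_slopes")
  expect_lt(at$p, 0.01)
  # single location bin falls back to the ANCOVA direction
  at1 <- random_slope_compare(rows$x, rows$y, rows$regime,
                              rep(50.2, nrow(rows)), rep(10.7, nrow(rows)))
  expect_true(at1$fallback)
  expect_identical(sign(at1$interaction), sign(at$interaction))
})

test_that("sensitivity-frost relation recovers a planted negative dependence", {
  set.seed(12)
  frost <- runif(80)
  sens <- 0.8 - 0.5 * frost + rnorm(80, 0, 0.05)
  rel <- sensitivity_vs_frost(sens, frost)
  expect_lt(rel$slope, 0)
  expect_lt(rel$p, 1e-6)
  expect_error(sensitivity_vs_frost(sens, rep(0.5, 80)), "zero variance")
})
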