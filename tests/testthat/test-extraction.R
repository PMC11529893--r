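# Senescence extraction: snow replacement, smoothing, the two dating rules,
# their combination, and MAD quality control.

test_that("fill_snow leaves unflagged series untouched and uses the winter mean", {
  vs <- make_curve_series()
  expect_identical(fill_snow(vs)$values, vs$values)

  # winter snow-free values {0.10, 0.12} across years -> flagged value 0.11
  dates <- as.Date(c("2000-01-10", "2000-07-10", "2001-01-10", "2001-07-10"))
  vs2 <- vi_series("x", dates, c(0.10, 0.6, 0.12, 0.02),
                   c(FALSE, FALSE, FALSE, TRUE))
  out <- fill_snow(vs2)
  expect_equal(out$values[4], 0.11)
  # the rule is unconditional on season: a flagged summer value is replaced too
  vs3 <- vi_series("x", dates, c(0.10, 0.6, 0.12, 0.5),
                   c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fill_snow(vs3)$values[2], 0.11)
  # no snow-free winter observation at all
  vs4 <- vi_series("x", dates, c(0.1, 0.6, 0.1, 0.6),
                   c(TRUE, FALSE, TRUE, FALSE))
  expect_error(fill_snow(vs4), "snow-free winter")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and damps spikes", {
  dates <- date_from_doy(2000, seq(1, 361, by = 15))
  n <- length(dates)
  const <- vi_series("x", dates, rep(0.4, n))
  expect_equal(smooth_series(const)$values, rep(0.4, n), tolerance = 1e-12)
  t <- seq_len(n)
  quad <- vi_series("x", dates, 0.2 + 0.01 * t + 0.002 * t^2)
  expect_equal(smooth_series(quad, 7, 3)$values, quad$values, tolerance = 1e-9)
  spike_vals <- rep(0.3, n); spike_vals[12] <- 0.9
  spike <- vi_series("x", dates, spike_vals)
  expect_lt(max(smooth_series(spike)$values[12]) - 0.3, 0.6)
  expect_error(smooth_series(const, window = 6), "odd")
  expect_error(smooth_series(const, window = 7, polyorder = 7), "polyorder")
  short <- vi_series("x", dates[1:5], rep(0.3, 5))
  expect_error(smooth_series(short), "shorter")
})

test_that("sparse-vegetation mask excludes below-threshold cells, strict inequality", {
  dates <- date_from_doy(2000, seq(1, 361, by = 15))
  n <- length(dates)
  expect_false(mask_sparse(vi_series("x", dates, rep(0.05, n))))
  expect_true(mask_sparse(vi_series("x", dates, rep(0.5, n))))
  expect_true(mask_sparse(vi_series("x", dates, rep(0.1, n))))  # boundary kept
})

test_that("double-logistic fit inverts noise-free curves", {
  truth <- c(a = -0.15, b = 0.3, c = -0.08, d = 120, e = 0.1, f = 280)
  vs <- make_curve_series(e = 0.1, f = 280)
  fit <- fit_double_logistic(vs)
  expect_true(fit$converged)
  expect_lt(max(abs(coef(fit) - truth) / abs(truth)), 1e-3)
  expect_lt(fit$rmse, 1e-8)
})

test_that("flat series does not converge; short series errors", {
  dates <- date_from_doy(2000, seq(1, 361, by = 15))
  flat <- vi_series("x", dates, rep(0.3, length(dates)))
  fit <- fit_double_logistic(flat)
  expect_false(fit$converged)
  short <- vi_series("x", dates[1:6], rep(0.3, 6))
  expect_error(fit_double_logistic(short), "at least 8")
})

test_that("second-derivative rule returns the second maximum of the decline", {
  # f = 280, e = 0.1: second-half maxima at f +/- ln(2+sqrt(3))/e
  vs <- make_curve_series(e = 0.1, f = 280)
  fit <- fit_double_logistic(vs)
  expect_equal(lsd_from_derivative(fit), 293L)
  # doubling the decline rate halves the offset from f
  vs2 <- make_curve_series(e = 0.2, f = 280)
  d2 <- lsd_from_derivative(fit_double_logistic(vs2))
  off1 <- 293 - 280
  expect_equal(d2 - 280, round_half_up(off1 / 2), tolerance = 1)
  expect_error(lsd_from_derivative(structure(list(converged = FALSE),
                                            class = "double_logistic_fit")),
               "converged")
})

test_that("threshold rule crosses at the half-amplitude point of the decline", {
  # noise-free logistic decline: half-amplitude crossing sits at f
  for (f in c(260, 285, 300)) {
    vs <- make_curve_series(f = f)
    expect_lt(abs(lsd_from_threshold(vs) - f), 1.5)
  }
  # observation exactly at ratio 0.5 on day 285 during the decline
  dates <- date_from_doy(2000, c(100, 150, 200, 285, 330, 360))
  vs <- vi_series("x", dates, c(0.2, 0.8, 0.8, 0.5, 0.25, 0.2))
  expect_identical(lsd_from_threshold(vs), 285L)
  const <- vi_series("x", dates, rep(0.3, 6))
  expect_error(lsd_from_threshold(const), "maximum")
})

test_that("combined senescence date averages the two rules, half-up", {
  expect_identical(combine_lsd(293L, 285L)$lsd, 289L)
  expect_identical(combine_lsd(290L, 290L)$lsd, 290L)
  one <- combine_lsd(291L, NA)
  expect_identical(one$lsd, 291L)
  expect_identical(one$method_flags, "derivative_only")
  expect_identical(combine_lsd(NA, NA)$method_flags, "none")
})

test_that("MAD filter matches hand-worked examples", {
  # median 281.5, MAD 1.0, bound 2.5 -> only 320 removed
  r <- mad_filter(c(280, 282, 281, 320))
  expect_identical(r$removed, 4L)
  expect_identical(r$retained, c(280, 282, 281))
  # median 280, MAD 10, bound 25 -> nothing removed
  r2 <- mad_filter(c(270, 280, 290))
  expect_length(r2$removed, 0)
  expect_length(mad_filter(rep(300, 5))$removed, 0)
  expect_error(mad_filter(c(1, 2)), "at least 3")
  expect_warning(r3 <- mad_filter(c(280, 280, 280, 300)), "zero")
  expect_identical(r3$retained, c(280, 280, 280))
})

test_that("MAD filter is idempotent and order-invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- round(rnorm(15, 280, 4))
    x[sample(15, 2)] <- x[sample(15, 2)] + sample(c(-40, 40), 2, replace = TRUE)
    r1 <- mad_filter(x)
    r2 <- suppressWarnings(mad_filter(r1$retained))
    # no new point beyond the recomputed bound -> second pass removes nothing
    med <- median(r1$retained)
    m <- median(abs(r1$retained - med))
    if (all(abs(r1$retained - med) <= 2.5 * m)) {
      expect_identical(r2$retained, r1$retained)
    }
    perm <- sample(length(x))
    expect_identical(sort(mad_filter(x[perm])$retained), sort(r1$retained))
  }
})

test_that("shifting a trajectory in time shifts both dating rules with it", {
  for (delta in c(10, 25)) {
    v1 <- make_curve_series(d = 120, f = 275)
    v2 <- make_curve_series(d = 120 + delta, f = 275 + delta)
    expect_lt(abs(lsd_from_threshold(v2) - lsd_from_threshold(v1) - delta), 1.5)
    d1 <- lsd_from_derivative(fit_double_logistic(v1))
    d2 <- lsd_from_derivative(fit_double_logistic(v2))
    expect_lt(abs(d2 - d1 - delta), 1.5)
  }
})

test_that("extract_lsd runs the chain and reports per-method dates", {
  cfg <- tiny_cfg(seed = 6, noise_sd_ndvi = 0.01, snow_prob = 0.2,
                  years = c(2000L, 2009L), trend_per_year = 0)
  ds <- generate_dataset(cfg)
  tab <- extract_lsd(ds$vi[[1]])
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$method_flags == "both"))
  expect_true(all(abs(tab$spread) < 40))
  merged <- merge(tab, ds$truth, by = "year")
  expect_lt(max(abs(merged$lsd_threshold - merged$lsd_true)), 9)
})
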