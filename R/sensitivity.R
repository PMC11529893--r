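# Warming/cooling regime detection, preseason selection, temperature
# sensitivities (ridge and multiple linear regression) and asymmetry tests.

#' Classify a period as warming, cooling or neither
#'
#' Autumn (Sep-Nov) mean temperature per year is regressed on year; the unit
#' is labelled `warming` for a significant positive slope, `cooling` for a
#' significant negative slope, `none` otherwise.
#'
#' @param series a [climate_series()].
#' @param period inclusive year range (length-2), default: all covered years.
#' @param alpha significance level.
#' @return list of class `regime_label`: `unit`, `period`, `regime`,
#'   `trend_slope`, `trend_p`.
#' @export
classify_regime <- function(series, period = NULL, alpha = 0.05) {
  stopifnot(inherits(series, "climate_series"))
  yrs <- sort(unique(as.integer(format(series$dates, "%Y"))))
  if (!is.null(period)) yrs <- yrs[yrs >= period[1] & yrs <= period[2]]
  vals <- vapply(yrs, function(y) autumn_mean_temperature(series, y), numeric(1))
  tr <- linear_trend(vals, yrs, alpha)
  regime <- if (!tr$significant) "none" else if (tr$slope > 0) "warming" else "cooling"
  structure(list(unit = series$id, period = range(yrs), regime = regime,
                 trend_slope = tr$slope, trend_p = tr$p),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("%s %d-%d: %s (%.3f degC/yr, p = %.3g)\n", x$unit,
              x$period[1], x$period[2], x$regime, x$trend_slope, x$trend_p))
  invisible(x)
}

#' Detect a warming/cooling shift between two periods
#'
#' @param series a [climate_series()].
#' @param period1,period2 inclusive year ranges.
#' @param alpha significance level.
#' @return `"warm_to_cool"`, `"cool_to_warm"`, or `"none"` (a shift requires
#'   both period regimes to be significant and opposite).
#' @export
classify_shift <- function(series, period1, period2, alpha = 0.05) {
  r1 <- classify_regime(series, period1, alpha)$regime
  r2 <- classify_regime(series, period2, alpha)$regime
  if (r1 == "warming" && r2 == "cooling") "warm_to_cool"
  else if (r1 == "cooling" && r2 == "warming") "cool_to_warm"
  else "none"
}

#' Moving-window regime detection along a senescence time series
#'
#' Slides a window of `window` years one year at a time over the span of the
#' senescence series, classifying each window's autumn temperature trend.
#'
#' @param series a [climate_series()].
#' @param lsd_df data.frame with columns `year`, `lsd`.
#' @param window window length in years.
#' @param alpha significance level.
#' @return data.frame with one row per window: `start`, `end`, `regime`,
#'   `trend_slope`, `trend_p`, `n_lsd` (senescence values inside the window).
#' @export
moving_window_regimes <- function(series, lsd_df, window = 15L, alpha = 0.05) {
  stopifnot(inherits(series, "climate_series"))
  yrs <- sort(unique(lsd_df$year))
  if (length(yrs) < window)
    stop(sprintf("unit %s: series shorter than the %d-year window", series$id, window))
  starts <- seq.int(min(yrs), max(yrs) - window + 1)
  rows <- lapply(starts, function(s) {
    rl <- classify_regime(series, c(s, s + window - 1), alpha)
    data.frame(start = s, end = s + window - 1, regime = rl$regime,
               trend_slope = rl$trend_slope, trend_p = rl$trend_p,
               n_lsd = sum(lsd_df$year >= s & lsd_df$year <= s + window - 1))
  })
  do.call(rbind, rows)
}

# Partial correlation of y and x controlling Z (residual-on-residual), with
# a t-based p-value on n - 2 - ncol(Z) degrees of freedom.
partial_cor <- function(y, x, Z) {
  ry <- stats::residuals(stats::lm(y ~ ., data = Z))
  rx <- stats::residuals(stats::lm(x ~ ., data = Z))
  r <- stats::cor(ry, rx)
  df <- length(y) - 2 - ncol(Z)
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df))
}

#' Select the optimal preseason window by partial correlation
#'
#' For each candidate length on the grid, correlates the annual senescence
#' dates with the window-mean temperature, controlling for the window
#' precipitation sum and mean radiation (residual-on-residual partial
#' correlation). Returns the length with the largest `|partial r|` among
#' those significant at `alpha`; ties go to the shortest window. The window
#' anchor is the unit's mean senescence date after MAD filtering.
#'
#' @param lsd_df data.frame with columns `year`, `lsd`.
#' @param climate matching [climate_series()].
#' @param grid candidate window lengths in days.
#' @param alpha significance level.
#' @param mad_k MAD-filter multiplier applied before anchoring.
#' @param anchor fixed window-end day-of-year; `NULL` (default) derives it
#'   from the MAD-filtered mean senescence date.
#' @return list of class `preseason_window`: `length` (`NA` when no window
#'   qualifies), `anchor`, `r`, `p`, and the full `table` of candidates.
#' @export
optimal_preseason <- function(lsd_df, climate, grid = seq(8L, 120L, by = 8L),
                              alpha = 0.05, mad_k = 2.5, anchor = NULL) {
  stopifnot(inherits(climate, "climate_series"))
  lsd_df <- lsd_df[stats::complete.cases(lsd_df[, c("year", "lsd")]), ]
  if (nrow(lsd_df) < 5) stop("need at least 5 complete years")
  keep <- mad_filter(lsd_df$lsd, mad_k)$kept
  if (is.null(anchor))
    anchor <- as.integer(round_half_up(mean(lsd_df$lsd[keep])))
  lsd_df <- lsd_df[keep, ]
  rows <- lapply(grid, function(L) {
    st <- lapply(lsd_df$year, function(y) preseason_stats(climate, L, anchor, y))
    Z <- data.frame(precip = vapply(st, `[[`, numeric(1), "precip_sum"),
                    rad = vapply(st, `[[`, numeric(1), "rad_mean"))
    x <- vapply(st, `[[`, numeric(1), "tmean_mean")
    pc <- partial_cor(lsd_df$lsd, x, Z)
    data.frame(length = L, r = pc$r, p = pc$p)
  })
  tab <- do.call(rbind, rows)
  ok <- tab[tab$p < alpha, , drop = FALSE]
  if (nrow(ok) == 0) {
    sel <- list(length = NA_integer_, r = NA_real_, p = NA_real_)
  } else {
    best <- max(abs(ok$r))
    cand <- ok[abs(ok$r) >= best - 1e-12, , drop = FALSE]
    cand <- cand[which.min(cand$length), ]
    sel <- list(length = as.integer(cand$length), r = cand$r, p = cand$p)
  }
  structure(c(sel, list(anchor = anchor, table = tab)),
            class = "preseason_window")
}

#' @export
print.preseason_window <- function(x, ...) {
  if (is.na(x$length)) {
    cat("Optimal preseason: none significant (unit excluded); anchor day",
        x$anchor, "\n")
  } else {
    cat(sprintf("Optimal preseason: %d days ending at day %d (partial r = %.3f, p = %.3g)\n",
                x$length, x$anchor, x$r, x$p))
  }
  invisible(x)
}

# Min-max scale anomalies of a vector to [0, 1]; NULL when degenerate.
scale01_anomaly <- function(v) {
  a <- v - mean(v)
  rng <- range(a)
  if (rng[2] == rng[1]) return(NULL)
  (a - rng[1]) / (rng[2] - rng[1])
}

# Ridge solution via SVD on a centered design (implicit intercept):
# beta = V diag(d / (d^2 + lambda)) U' y.
ridge_solve <- function(X, y, lambda) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  drop(sv$v %*% ((sv$d / (sv$d^2 + lambda)) * crossprod(sv$u, yc)))
}

# Generalized cross-validation for the ridge penalty on a centered design.
ridge_gcv <- function(X, y, lambdas = 10^seq(-4, 3, length.out = 40)) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sv <- svd(Xc)
  n <- length(y)
  uy <- crossprod(sv$u, yc)
  scores <- vapply(lambdas, function(l) {
    shrink <- sv$d^2 / (sv$d^2 + l)
    fit <- sv$u %*% (shrink * uy)
    rss <- sum((yc - fit)^2)
    df <- 1 + sum(shrink)
    n * rss / (n - df)^2
  }, numeric(1))
  lambdas[which.min(scores)]
}

#' Ridge-regression temperature sensitivity on normalized anomalies
#'
#' Anomalies of the response and of each covariate (temperature,
#' precipitation, radiation) are min-max normalized to \[0, 1\] per
#' variable; the ridge solution on the (centered) normalized design gives a
#' dimensionless temperature coefficient. The penalty defaults to the
#' generalized-cross-validation minimizer; the standard error comes from
#' seeded case-resampling bootstrap.
#'
#' @param lsd annual response values (senescence dates).
#' @param covars data.frame with columns `temp`, `precip`, `rad` (annual
#'   window covariates, same length as `lsd`).
#' @param lambda ridge penalty; `NULL` selects it by GCV.
#' @param n_boot bootstrap resamples for the SE.
#' @param boot_seed seed of the bootstrap stream (`NULL`: use the current
#'   RNG state).
#' @return list of class `sensitivity_result`: `method = "ridge"`, `slope`
#'   (temperature coefficient, dimensionless), `se`, `p` (normal
#'   approximation from the bootstrap SE), `lambda`, `coefficients`,
#'   `dropped` (zero-variance covariates removed), `n`.
#' @export
ridge_sensitivity <- function(lsd, covars, lambda = NULL, n_boot = 1000L,
                              boot_seed = NULL) {
  stopifnot(is.data.frame(covars),
            all(c("temp", "precip", "rad") %in% names(covars)),
            nrow(covars) == length(lsd))
  if (length(lsd) < 5) stop("need at least 5 years")
  cols <- lapply(covars[c("temp", "precip", "rad")], scale01_anomaly)
  dropped <- names(cols)[vapply(cols, is.null, logical(1))]
  if ("temp" %in% dropped) stop("temperature covariate has zero variance")
  if (length(dropped))
    warning("zero-variance covariate(s) dropped: ", paste(dropped, collapse = ", "))
  cols <- cols[!vapply(cols, is.null, logical(1))]
  X <- do.call(cbind, cols)
  ys <- scale01_anomaly(lsd)
  if (is.null(ys)) stop("response has zero variance")
  if (is.null(lambda)) lambda <- ridge_gcv(X, ys)
  beta <- ridge_solve(X, ys, lambda)
  names(beta) <- colnames(X)
  bs <- with_seed(boot_seed, {
    n <- length(ys)
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (any(apply(Xb, 2, function(v) diff(range(v))) == 0)) return(NA_real_)
      ridge_solve(Xb, ys[idx], lambda)[1]
    }, numeric(1))
  })
  se <- stats::sd(bs, na.rm = TRUE)
  structure(list(method = "ridge", slope = unname(beta["temp"]), se = se,
                 p = 2 * stats::pnorm(-abs(beta["temp"]) / se),
                 lambda = lambda, coefficients = beta, dropped = dropped,
                 n = length(ys)),
            class = "sensitivity_result")
}

#' Multiple-linear-regression temperature sensitivity
#'
#' Unscaled OLS of the response on window temperature, precipitation and
#' radiation; the temperature coefficient is the sensitivity in response
#' units per degree C.
#'
#' @param lsd annual response values.
#' @param covars data.frame with columns `temp`, `precip`, `rad`.
#' @return list of class `sensitivity_result`: `method = "mlr"`, `slope`
#'   (units/degC), `se`, `p`, `ci` (95%), `n`.
#' @export
mlr_sensitivity <- function(lsd, covars) {
  stopifnot(is.data.frame(covars),
            all(c("temp", "precip", "rad") %in% names(covars)),
            nrow(covars) == length(lsd))
  if (length(lsd) < 6) stop("need at least 6 years for three covariates")
  X <- stats::model.matrix(~ temp + precip + rad, covars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  fit <- stats::lm(lsd ~ temp + precip + rad, data = covars)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)["temp", ]
  structure(list(method = "mlr", slope = unname(sm["temp", "Estimate"]),
                 se = unname(sm["temp", "Std. Error"]),
                 p = unname(sm["temp", "Pr(>|t|)"]),
                 ci = unname(ci), n = length(lsd)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("%s temperature sensitivity: %.3f +/- %.3f (p = %.3g, n = %d)\n",
              x$method, x$slope, x$se, x$p, x$n))
  invisible(x)
}

new_asymmetry_test <- function(method, statistic, p, ...) {
  structure(c(list(method = method, statistic = statistic, p = p), list(...)),
            class = "asymmetry_test")
}

#' @export
print.asymmetry_test <- function(x, ...) {
  cat(sprintf("Asymmetry test (%s): statistic = %.3f, p = %.3g\n",
              x$method, x$statistic, x$p))
  if (!is.null(x$means))
    cat(sprintf("  group means: %.3f (warming) vs %.3f (cooling)\n",
                x$means[1], x$means[2]))
  invisible(x)
}

#' Two-sample t-test on unit-level sensitivities by regime
#'
#' Student's t-test (equal variances) of warming-group versus cooling-group
#' temperature sensitivities, with group means and standard errors.
#'
#' @param slopes unit-level temperature sensitivities.
#' @param regime matching labels, `"warming"` / `"cooling"`.
#' @return an `asymmetry_test` (method `t_test`) with `means`, `ses`, `ns`.
#' @export
group_sensitivities <- function(slopes, regime) {
  stopifnot(length(slopes) == length(regime))
  w <- slopes[regime == "warming"]
  c_ <- slopes[regime == "cooling"]
  if (length(w) < 2 || length(c_) < 2)
    stop("each regime group needs at least 2 units")
  tt <- stats::t.test(w, c_, var.equal = TRUE)
  new_asymmetry_test("t_test", unname(tt$statistic), tt$p.value,
                     means = c(warming = mean(w), cooling = mean(c_)),
                     ses = c(warming = stats::sd(w) / sqrt(length(w)),
                             cooling = stats::sd(c_) / sqrt(length(c_))),
                     ns = c(warming = length(w), cooling = length(c_)))
}

#' Slope comparison by covariance analysis
#'
#' Fits `y ~ x * group` and tests the interaction term: equality of the
#' regression slopes between the two groups.
#'
#' @param x predictor values (e.g., cold-degree days).
#' @param y response values (e.g., senescence dates).
#' @param group two-level factor/labels.
#' @return an `asymmetry_test` (method `ancova_slopes`) with `slopes` per
#'   group and `interaction` estimate.
#' @export
compare_slopes_ancova <- function(x, y, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2 || any(table(group) < 3))
    stop("need two groups with at least 3 observations each")
  fit <- stats::lm(y ~ x * group)
  sm <- summary(fit)$coefficients
  irow <- grep(":", rownames(sm))
  slopes <- c(sm["x", "Estimate"], sm["x", "Estimate"] + sm[irow, "Estimate"])
  names(slopes) <- levels(group)
  new_asymmetry_test("ancova_slopes", unname(sm[irow, "t value"]),
                     unname(sm[irow, "Pr(>|t|)"]),
                     slopes = slopes, interaction = unname(sm[irow, "Estimate"]))
}

#' Regime contrast with random intercepts among biomes
#'
#' Linear mixed model `metric ~ regime + (1 | biome)`; the fixed regime
#' contrast and its Satterthwaite p-value are reported. With a single biome
#' the model degenerates to an OLS contrast (flagged).
#'
#' @param values unit-level metric values.
#' @param regime warming/cooling labels.
#' @param biome biome labels (random-intercept grouping).
#' @return an `asymmetry_test` (method `mixed_intercepts`) with `contrast`
#'   and `fallback` flag.
#' @export
mixed_compare <- function(values, regime, biome) {
  stopifnot(length(values) == length(regime), length(values) == length(biome))
  regime <- factor(regime, levels = c("cooling", "warming"))
  if (length(unique(biome)) < 2) {
    fit <- stats::lm(values ~ regime)
    sm <- summary(fit)$coefficients
    return(new_asymmetry_test("mixed_intercepts", unname(sm[2, "t value"]),
                              unname(sm[2, "Pr(>|t|)"]),
                              contrast = unname(sm[2, "Estimate"]),
                              fallback = TRUE))
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(values ~ regime + (1 | biome),
                   data = data.frame(values, regime, biome))))
  sm <- stats::coef(summary(fit))
  new_asymmetry_test("mixed_intercepts", unname(sm[2, "t value"]),
                     unname(sm[2, "Pr(>|t|)"]),
                     contrast = unname(sm[2, "Estimate"]), fallback = FALSE)
}

#' Regime slope contrast with location random slopes
#'
#' Linear mixed model `y ~ x * regime + (x | location)` where location is
#' latitude/longitude binned to `bin`-degree cells; reports the interaction
#' (regime difference in the x-slope). With a single location bin the model
#' degenerates to [compare_slopes_ancova()] (flagged).
#'
#' @param x predictor (e.g., cold-degree days).
#' @param y response (e.g., senescence dates).
#' @param regime warming/cooling labels.
#' @param lat,lon unit coordinates, degrees.
#' @param bin bin width in degrees for the random-effect grouping.
#' @return an `asymmetry_test` (method `random_slopes`).
#' @export
random_slope_compare <- function(x, y, regime, lat, lon, bin = 1) {
  loc <- paste(floor(lat / bin), floor(lon / bin), sep = ":")
  regime <- factor(regime, levels = c("cooling", "warming"))
  if (length(unique(loc)) < 2) {
    res <- compare_slopes_ancova(x, y, regime)
    res$method <- "random_slopes"
    res$fallback <- TRUE
    return(res)
  }
  dat <- data.frame(x, y, regime, loc)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ x * regime + (x | loc), data = dat)))
  sm <- stats::coef(summary(fit))
  irow <- grep(":", rownames(sm))
  new_asymmetry_test("random_slopes", unname(sm[irow, "t value"]),
                     unname(sm[irow, "Pr(>|t|)"]),
                     interaction = unname(sm[irow, "Estimate"]),
                     fallback = FALSE)
}

#' Relation between temperature sensitivity and frost risk
#'
#' OLS of absolute ridge sensitivities on the frost risk index across units.
#'
#' @param sens unit-level ridge temperature sensitivities (absolute values
#'   are taken).
#' @param frost matching frost risk indices.
#' @return list with `slope`, `p`, `r2`, `n`.
#' @export
sensitivity_vs_frost <- function(sens, frost) {
  stopifnot(length(sens) == length(frost))
  if (stats::var(frost) == 0) stop("frost risk index has zero variance")
  fit <- stats::lm(abs(sens) ~ frost)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       p = unname(sm$coefficients[2, "Pr(>|t|)"]),
       r2 = sm$r.squared, n = length(sens))
}
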