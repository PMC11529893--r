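# Senescence-date extraction from vegetation-index trajectories, and
# quality control of in-situ senescence records.

#' Replace snow-contaminated observations by the winter baseline
#'
#' Every flagged value is replaced by the across-all-years December-February
#' mean of snow-free values; unflagged values are untouched. The rule is
#' applied to flagged observations in any season.
#'
#' @param series a [vi_series()].
#' @return a [vi_series()] with flagged values replaced (flags are kept).
#' @export
fill_snow <- function(series) {
  stopifnot(inherits(series, "vi_series"))
  winter_free <- is_winter(series$dates) & !series$snow
  if (!any(winter_free))
    stop(sprintf("cell %s has no snow-free winter observation", series$id))
  fill <- mean(series$values[winter_free])
  out <- series
  out$values[out$snow] <- fill
  out
}

#' Savitzky-Golay smoothing of a vegetation-index series
#'
#' @param series a [vi_series()].
#' @param window odd filter length (observations).
#' @param polyorder polynomial order, `< window`.
#' @return a [vi_series()] with smoothed values; dates unchanged.
#' @export
smooth_series <- function(series, window = 7L, polyorder = 3L) {
  stopifnot(inherits(series, "vi_series"))
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (length(series$values) < window)
    stop("series shorter than the smoothing window")
  out <- series
  out$values <- as.numeric(signal::sgolayfilt(series$values, p = polyorder,
                                              n = window))
  out
}

#' Sparse-vegetation mask
#'
#' A cell is kept only when its mean annual vegetation index reaches the
#' threshold; `mean annual` is the mean of per-year means. The comparison is
#' strict: a mean exactly at the threshold is kept.
#'
#' @param series a [vi_series()].
#' @param threshold index value below which the cell is excluded.
#' @return `TRUE` to keep the cell, `FALSE` to exclude it.
#' @export
mask_sparse <- function(series, threshold = 0.1) {
  stopifnot(inherits(series, "vi_series"))
  yr <- as.integer(format(series$dates, "%Y"))
  annual <- tapply(series$values, yr, mean)
  !(mean(annual) < threshold)
}

# Analytic second derivative of the double logistic w.r.t. time. For each
# sigmoid s(t) = 1/(1+u), u = exp(k (t-m)): s'' = k^2 u (u-1) / (1+u)^3.
dl_second_derivative <- function(t, a, b, c, d, e, f) {
  term <- function(k, m) {
    u <- exp(pmin(700, k * (t - m)))
    k^2 * u * (u - 1) / (1 + u)^3
  }
  b * (term(c, d) + term(e, f))
}

#' Fit the double-logistic greenness model to one year of observations
#'
#' Fits `y(t) = a + b (1/(1+exp(c (t-d))) + 1/(1+exp(e (t-f))))` by
#' Levenberg-Marquardt nonlinear least squares, with bounds enforcing the
#' sign convention `c < 0` (green-up sigmoid) and `e > 0` (senescence
#' sigmoid) so `d` and `f` are the green-up and senescence inflection dates.
#' Initial values are data-driven (amplitude from the 5th/95th percentiles,
#' inflections from the largest positive/negative first differences) with a
#' deterministic set of jittered restarts; the best-SSE converged fit wins.
#'
#' @param series a [vi_series()] holding one calendar year of observations
#'   covering both halves of the year.
#' @return an object of class `double_logistic_fit`: coefficients `a, b, c,
#'   d, e, f`, `rmse`, and `converged` (`FALSE` when the optimizer fails, the
#'   amplitude is not positive, or the inflection order `d < f` is violated).
#' @export
fit_double_logistic <- function(series) {
  stopifnot(inherits(series, "vi_series"))
  t <- doy(series$dates)
  y <- series$values
  if (length(t) < 8) stop("need at least 8 observations to fit the double logistic")
  if (max(t) < 183 || min(t) > 182)
    stop("observations must cover both halves of the year")
  q <- stats::quantile(y, c(0.05, 0.95), names = FALSE)
  b0 <- max(q[2] - q[1], 1e-3)
  a0 <- q[1] - b0
  dy <- diff(y)
  d0 <- t[which.max(dy)]
  f0 <- t[which.min(dy) + 1]
  if (f0 <= d0) { d0 <- stats::quantile(t, 0.25, names = FALSE); f0 <- stats::quantile(t, 0.75, names = FALSE) }
  jitters <- list(c(0, 0), c(-15, 15), c(15, -15), c(-30, 30))
  lower <- c(a = -1, b = 1e-6, c = -2, d = 1, e = 1e-4, f = 1)
  upper <- c(a = 1.5, b = 2, c = -1e-4, d = 366, e = 2, f = 366)
  best <- NULL
  for (j in jitters) {
    st <- list(a = a0, b = b0, c = -0.1,
               d = min(max(d0 + j[1], 2), 365),
               e = 0.1, f = min(max(f0 + j[2], 2), 365))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + b * (1 / (1 + exp(c * (t - d))) + 1 / (1 + exp(e * (t - f)))),
        start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(coefficients = NULL, rmse = NA_real_,
                          converged = FALSE, year = NULL),
                     class = "double_logistic_fit"))
  }
  p <- as.list(stats::coef(best$fit))
  converged <- p$b > 1e-5 && p$d < p$f
  structure(list(coefficients = unlist(p),
                 rmse = sqrt(best$rss / length(y)),
                 converged = converged,
                 year = as.integer(format(series$dates[1], "%Y"))),
            class = "double_logistic_fit")
}

#' @export
print.double_logistic_fit <- function(x, ...) {
  if (is.null(x$coefficients)) {
    cat("Double-logistic fit: optimizer failed\n")
    return(invisible(x))
  }
  cat("Double-logistic fit", if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$coefficients, 4))
  cat(sprintf("rmse = %.5f\n", x$rmse))
  invisible(x)
}

#' @export
coef.double_logistic_fit <- function(object, ...) object$coefficients

#' @export
predict.double_logistic_fit <- function(object, t, ...) {
  p <- as.list(object$coefficients)
  double_logistic(t, p$a, p$b, p$c, p$d, p$e, p$f)
}

#' Senescence date from the second-derivative rule
#'
#' Evaluates the analytic second derivative of the fitted curve on a daily
#' grid restricted to the second half of the year (day-of-year > 182), finds
#' its local maxima, and returns the second one by date. When only one
#' maximum falls in the window it is returned with a flag; with none, the
#' method fails and `NA` is returned.
#'
#' @param fit a converged [fit_double_logistic()] result.
#' @return integer day-of-year, possibly `NA`; attribute `"single_max"` marks
#'   a flagged single-maximum estimate.
#' @export
lsd_from_derivative <- function(fit) {
  stopifnot(inherits(fit, "double_logistic_fit"))
  if (!isTRUE(fit$converged)) stop("fit has not converged")
  p <- as.list(fit$coefficients)
  t <- 183:365
  y2 <- dl_second_derivative(t, p$a, p$b, p$c, p$d, p$e, p$f)
  n <- length(y2)
  ismax <- c(FALSE, y2[2:(n - 1)] > y2[1:(n - 2)] & y2[2:(n - 1)] > y2[3:n], FALSE)
  peaks <- t[ismax]
  if (length(peaks) == 0) return(NA_integer_)
  if (length(peaks) == 1)
    return(structure(as.integer(peaks), single_max = TRUE))
  as.integer(peaks[2])
}

#' Senescence date from the dynamic amplitude threshold
#'
#' Computes the annual greenness ratio `(v - min) / (max - min)` and returns
#' the first date after the annual maximum at which the ratio crosses 0.5
#' downward, linearly interpolated between the bracketing observations and
#' rounded half-up to the nearest day.
#'
#' @param series a [vi_series()] holding one calendar year of (smoothed)
#'   observations.
#' @param threshold crossing fraction of the annual amplitude.
#' @return integer day-of-year, or `NA` when the ratio never falls below the
#'   threshold after the maximum.
#' @export
lsd_from_threshold <- function(series, threshold = 0.5) {
  stopifnot(inherits(series, "vi_series"))
  v <- series$values
  t <- doy(series$dates)
  if (max(v) <= min(v)) stop("annual maximum must exceed the minimum")
  r <- (v - min(v)) / (max(v) - min(v))
  i0 <- which.max(v)
  for (i in seq.int(i0, length(r) - 1)) {
    if (r[i] >= threshold && r[i + 1] < threshold) {
      if (r[i] == threshold) return(as.integer(t[i]))
      cross <- t[i] + (r[i] - threshold) / (r[i] - r[i + 1]) * (t[i + 1] - t[i])
      return(as.integer(round_half_up(cross)))
    }
  }
  NA_integer_
}

#' Combine the two senescence-date estimates
#'
#' The reported LSD is the arithmetic mean of the derivative-rule and
#' threshold-rule dates, rounded half-up. When one method failed the other is
#' used alone and flagged.
#'
#' @param d1 day-of-year from the derivative rule (`NA` on failure).
#' @param d2 day-of-year from the threshold rule (`NA` on failure).
#' @return list with `lsd` (integer day-of-year or `NA`), `method_flags`
#'   (character: `"both"`, `"derivative_only"`, `"threshold_only"`,
#'   `"none"`), and `spread` (absolute difference when both succeeded).
#' @export
combine_lsd <- function(d1, d2) {
  ok1 <- !is.na(d1); ok2 <- !is.na(d2)
  if (ok1 && ok2) {
    list(lsd = as.integer(round_half_up((as.numeric(d1) + as.numeric(d2)) / 2)),
         method_flags = "both", spread = abs(as.numeric(d1) - as.numeric(d2)))
  } else if (ok1) {
    list(lsd = as.integer(d1), method_flags = "derivative_only", spread = NA_real_)
  } else if (ok2) {
    list(lsd = as.integer(d2), method_flags = "threshold_only", spread = NA_real_)
  } else {
    list(lsd = NA_integer_, method_flags = "none", spread = NA_real_)
  }
}

#' Median-absolute-deviation outlier filter
#'
#' For a senescence-date series, `MAD = median(|x - median(x)|)` (no
#' consistency constant); values with `|x - median(x)| > k * MAD` are removed
#' in a single pass. When `MAD = 0` but values differ, only values equal to
#' the median are retained and the degenerate case is signalled with a
#' warning.
#'
#' @param values numeric vector (>= 3 values).
#' @param k multiplier on the MAD defining the outlier bound.
#' @return list with `retained` (values), `removed` (indices into the input),
#'   and `kept` (logical mask).
#' @export
mad_filter <- function(values, k = 2.5) {
  if (length(values) < 3) stop("mad_filter needs at least 3 values")
  med <- stats::median(values)
  dev <- abs(values - med)
  m <- stats::median(dev)
  if (m == 0 && any(dev > 0)) {
    warning("MAD is zero with non-identical values; retaining only values equal to the median")
    kept <- dev == 0
  } else {
    kept <- dev <= k * m
  }
  list(retained = values[kept], removed = which(!kept), kept = kept)
}

#' One-calendar-year slice of a vegetation-index series
#'
#' @param series a [vi_series()].
#' @param year calendar year to keep.
#' @return a [vi_series()] restricted to that year.
#' @export
vi_year <- function(series, year) {
  sel <- as.integer(format(series$dates, "%Y")) == year
  vi_series(series$id, series$dates[sel], series$values[sel], series$snow[sel])
}

#' Extract annual senescence dates for one cell
#'
#' Full per-cell chain: sparse-vegetation mask, snow replacement,
#' Savitzky-Golay reconstruction, then per year a double-logistic fit with
#' the second-derivative rule plus the dynamic-threshold rule on the smoothed
#' observations, combined by averaging.
#'
#' @param series a multi-year [vi_series()].
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param mask_threshold sparse-vegetation threshold.
#' @param threshold amplitude fraction of the dynamic-threshold rule.
#' @return data.frame with columns `cell_id`, `year`, `lsd_derivative`,
#'   `lsd_threshold`, `lsd`, `method_flags`, `spread`; `NULL` when the cell
#'   is masked out as sparse vegetation.
#' @export
extract_lsd <- function(series, sg_window = 7L, sg_polyorder = 3L,
                        mask_threshold = 0.1, threshold = 0.5) {
  stopifnot(inherits(series, "vi_series"))
  if (!mask_sparse(series, mask_threshold)) return(NULL)
  sm <- smooth_series(fill_snow(series), sg_window, sg_polyorder)
  years <- sort(unique(as.integer(format(sm$dates, "%Y"))))
  rows <- lapply(years, function(y) {
    ys <- vi_year(sm, y)
    d1 <- tryCatch({
      fit <- fit_double_logistic(ys)
      if (isTRUE(fit$converged)) lsd_from_derivative(fit) else NA_integer_
    }, error = function(e) NA_integer_)
    d2 <- tryCatch(lsd_from_threshold(ys, threshold),
                   error = function(e) NA_integer_)
    cmb <- combine_lsd(d1, d2)
    data.frame(cell_id = series$id, year = y,
               lsd_derivative = as.integer(d1), lsd_threshold = as.integer(d2),
               lsd = cmb$lsd, method_flags = cmb$method_flags,
               spread = cmb$spread)
  })
  do.call(rbind, rows)
}
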