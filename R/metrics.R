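# Climate forcing and stress metrics: cold-degree days, preseason
# statistics, frost risk, kNDVI, autumn means and trends.

#' Daily cold-degree-day contribution
#'
#' `max(tbase - tdaily, 0)`: the daily shortfall of mean temperature below
#' the base temperature, in degC day.
#'
#' @param tdaily daily mean temperature, degC (vectorised).
#' @param tbase base temperature, degC.
#' @return degC day values.
#' @export
cdd_daily <- function(tdaily, tbase) {
  pmax(tbase - tdaily, 0)
}

#' Accumulated cold-degree days from July 1 to the senescence date
#'
#' Sums [cdd_daily()] over July 1 through the year's senescence date,
#' inclusive. Conventional base temperatures are 5, 10 and 15 degC.
#'
#' @param series a [climate_series()].
#' @param year calendar year.
#' @param lsd senescence day-of-year (must not precede July 1).
#' @param tbase base temperature, degC.
#' @return accumulated cold-degree days (degC day).
#' @export
cdd_accumulate <- function(series, year, lsd, tbase) {
  stopifnot(inherits(series, "climate_series"))
  jul1 <- date_from_doy(year, doy(as.Date(sprintf("%d-07-01", year))))
  end <- date_from_doy(year, lsd)
  if (end < jul1) stop(sprintf("senescence date of year %d precedes July 1", year))
  sel <- series$dates >= jul1 & series$dates <= end
  if (!any(sel)) stop(sprintf("year %d not covered by the climate series", year))
  sum(cdd_daily(series$tmean[sel], tbase))
}

#' Preseason climate statistics
#'
#' Statistics over the window of `length` days ending at the anchor
#' day-of-year of the given year: mean and SD of daily mean temperature,
#' precipitation sum, mean radiation, count of frost days (minimum
#' temperature strictly below 0 degC), and mean monthly SPEI over every
#' month that overlaps the window (a month counts if any window day falls
#' in it).
#'
#' @param series a [climate_series()].
#' @param length window length in days.
#' @param anchor window end, day-of-year (typically the unit's mean LSD).
#' @param year calendar year.
#' @return list with `tmean_mean`, `tmean_sd`, `precip_sum`, `rad_mean`,
#'   `frost_days`, `spei_mean`.
#' @export
preseason_stats <- function(series, length, anchor, year) {
  stopifnot(inherits(series, "climate_series"), length >= 1)
  win <- date_from_doy(year, seq.int(anchor - length + 1, anchor))
  # complete-daily-calendar invariant allows O(1) index arithmetic
  sel <- as.integer(win - series$dates[1]) + 1L
  if (sel[1] < 1 || sel[length(sel)] > base::length(series$dates))
    stop(sprintf("preseason window of year %d falls outside the climate series", year))
  mk <- unique(as.integer(format(win, "%Y")) * 12L + as.integer(format(win, "%m")))
  sm <- series$spei$spei[(series$spei$year * 12L + series$spei$month) %in% mk]
  list(
    tmean_mean = mean(series$tmean[sel]),
    tmean_sd = stats::sd(series$tmean[sel]),
    precip_sum = sum(series$precip[sel]),
    rad_mean = mean(series$radiation[sel]),
    frost_days = sum(series$tmin[sel] < 0),
    spei_mean = if (base::length(sm)) mean(sm) else NA_real_
  )
}

#' Frost risk index
#'
#' Min-max standardization of per-cell mean preseason frost-day counts over
#' the pooled population of analyzed (warming + cooling) cells:
#' `(x - min) / (max - min)`, in \[0, 1\]. With a degenerate population
#' (max = min) all indices are 0.
#'
#' @param counts per-cell mean frost-day counts.
#' @return frost risk index per cell.
#' @export
frost_risk_index <- function(counts) {
  if (length(counts) == 0) stop("population of cells is empty")
  rng <- range(counts)
  if (rng[2] == rng[1]) return(rep(0, length(counts)))
  (counts - rng[1]) / (rng[2] - rng[1])
}

#' Kernel NDVI
#'
#' `kNDVI = tanh(NDVI^2)`, a greenness-based productivity proxy.
#'
#' @param ndvi NDVI values.
#' @return kNDVI values.
#' @export
kndvi <- function(ndvi) {
  tanh(ndvi^2)
}

#' Mean autumn (September-November) temperature of one year
#'
#' @param series a [climate_series()].
#' @param year calendar year.
#' @return mean of daily mean temperature over Sep 1 - Nov 30, degC.
#' @export
autumn_mean_temperature <- function(series, year) {
  stopifnot(inherits(series, "climate_series"))
  span <- seq(as.Date(sprintf("%d-09-01", year)),
              as.Date(sprintf("%d-11-30", year)), by = "day")
  sel <- as.integer(span - series$dates[1]) + 1L
  if (sel[1] < 1 || sel[length(sel)] > length(series$dates))
    stop(sprintf("autumn of year %d is not fully covered by the climate series", year))
  mean(series$tmean[sel])
}

#' Linear least-squares trend of an annual series
#'
#' OLS of value on year with a two-sided test of zero slope.
#'
#' @param values annual values.
#' @param years matching calendar years (defaults to consecutive integers).
#' @param alpha significance level.
#' @return list with `slope` (unit/yr), `p`, `significant`.
#' @export
linear_trend <- function(values, years = seq_along(values), alpha = 0.05) {
  if (length(values) < 3) stop("need at least 3 years for a trend")
  fit <- stats::lm(values ~ years)
  sm <- suppressWarnings(summary(fit))$coefficients  # constant series: perfect fit
  slope <- sm["years", "Estimate"]
  p <- sm["years", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1  # zero-residual degenerate series
  list(slope = unname(slope), p = unname(p), significant = p < alpha)
}
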