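# Scenario configuration for the synthetic-data generator.

#' Scenario configuration for synthetic phenology data
#'
#' Defines the study conditions the generator emulates: a network of
#' independent sites/grid cells with coupled daily climate, bi-weekly
#' greenness, annual senescence dates and autumn productivity, where leaf
#' senescence date (LSD) responds to preseason temperature through a
#' piecewise-linear hinge — one planted sensitivity for warm anomalies
#' (days delayed per degree C of warming) and another for cold anomalies
#' (days advanced per degree C of cooling).
#'
#' @param n_sites number of independent sites/grid cells (>= 1).
#' @param years inclusive calendar-year range, length-2 integer vector.
#' @param regime temperature-trend regime: `"warming"`, `"cooling"`,
#'   `"mixed"` (sites alternate warming/cooling), or `"shift"` (trend
#'   reverses halfway through the record).
#' @param trend_per_year magnitude of the autumn temperature trend, degrees C
#'   per year.
#' @param planted_sens_warm LSD response to warm preseason anomalies,
#'   days/degree C (>= 0; positive = delay).
#' @param planted_sens_cool LSD response to cold preseason anomalies,
#'   days/degree C (>= 0; positive = advance under cooling).
#' @param base_lsd climatological senescence date, day-of-year.
#' @param preseason_len_true length (days) of the temperature window that
#'   truly drives LSD in the generator.
#' @param noise_sd_lsd interannual LSD observation noise, days (SD).
#' @param noise_sd_ndvi additive vegetation-index noise (SD, index units).
#' @param snow_prob probability that a winter (Dec-Feb) observation is
#'   snow-contaminated.
#' @param frost_rate expected number of preseason days with minimum
#'   temperature below 0 degrees C (per year); the Tmin offset is calibrated
#'   to hit it in expectation.
#' @param spei_mean mean of the generated monthly SPEI (dimensionless;
#'   drawn Normal(spei_mean, 1), truncated to \[-3, 3\]).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param cadence_days vegetation-index sampling interval in days.
#' @param ar1_phi lag-1 autocorrelation of daily temperature noise.
#' @param temp_noise_sd marginal SD of daily temperature noise, degrees C.
#' @param vi_amplitude seasonal greenness amplitude `b` of the
#'   double-logistic forward model (index units).
#' @param vi_background offset `a` of the double-logistic forward model.
#' @param vi_rate_up,vi_rate_down rate parameters of the green-up (`c`,
#'   negative) and senescence (`e`, positive) sigmoids, 1/day.
#' @param vi_greenup_doy green-up inflection day-of-year `d`.
#' @param prod_baseline baseline autumn productivity (g C m^-2 per autumn).
#' @param prod_gamma coupling of autumn productivity to LSD displacement,
#'   g C m^-2 per day of delay.
#' @param prod_temp_coef direct temperature effect on autumn productivity,
#'   g C m^-2 per degree C.
#' @param noise_sd_prod productivity noise SD (g C m^-2).
#' @return an object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(n_sites = 4, years = c(2000, 2019), seed = 1)
#' cfg$planted_sens_warm
#' @export
scenario_config <- function(n_sites = 100L,
                            years = c(1989L, 2018L),
                            regime = c("mixed", "warming", "cooling", "shift"),
                            trend_per_year = 0.1,
                            planted_sens_warm = 7.5,
                            planted_sens_cool = 3.3,
                            base_lsd = 285L,
                            preseason_len_true = 40L,
                            noise_sd_lsd = 5,
                            noise_sd_ndvi = 0.02,
                            snow_prob = 0.3,
                            frost_rate = 2,
                            spei_mean = 0,
                            seed = 1L,
                            cadence_days = 15L,
                            ar1_phi = 0.7,
                            temp_noise_sd = 2,
                            vi_amplitude = 0.3,
                            vi_background = -0.15,
                            vi_rate_up = -0.08,
                            vi_rate_down = 0.08,
                            vi_greenup_doy = 120,
                            prod_baseline = 300,
                            prod_gamma = 2,
                            prod_temp_coef = 3,
                            noise_sd_prod = 10) {
  regime <- match.arg(regime)
  stopifnot(
    length(n_sites) == 1, n_sites >= 1,
    length(years) == 2, years[2] >= years[1],
    trend_per_year >= 0 || regime == "mixed",
    planted_sens_warm >= 0, planted_sens_cool >= 0,
    base_lsd >= 1, base_lsd <= 366,
    preseason_len_true >= 1, preseason_len_true < base_lsd,
    noise_sd_lsd >= 0, noise_sd_ndvi >= 0,
    snow_prob >= 0, snow_prob <= 1,
    frost_rate >= 0,
    cadence_days >= 1,
    abs(ar1_phi) < 1, temp_noise_sd > 0
  )
  n_years <- years[2] - years[1] + 1
  if (regime %in% c("warming", "cooling", "shift", "mixed") &&
      trend_per_year > 0 && n_years < 15) {
    stop("regimes with a planted trend need a year span of at least 15 years")
  }
  cfg <- list(
    n_sites = as.integer(n_sites), years = as.integer(years), regime = regime,
    trend_per_year = trend_per_year,
    planted_sens_warm = planted_sens_warm,
    planted_sens_cool = planted_sens_cool,
    base_lsd = as.integer(base_lsd),
    preseason_len_true = as.integer(preseason_len_true),
    noise_sd_lsd = noise_sd_lsd, noise_sd_ndvi = noise_sd_ndvi,
    snow_prob = snow_prob, frost_rate = frost_rate, spei_mean = spei_mean,
    seed = as.integer(seed), cadence_days = as.integer(cadence_days),
    ar1_phi = ar1_phi, temp_noise_sd = temp_noise_sd,
    vi_amplitude = vi_amplitude, vi_background = vi_background,
    vi_rate_up = vi_rate_up, vi_rate_down = vi_rate_down,
    vi_greenup_doy = vi_greenup_doy,
    prod_baseline = prod_baseline, prod_gamma = prod_gamma,
    prod_temp_coef = prod_temp_coef, noise_sd_prod = noise_sd_prod
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Synthetic scenario:", x$n_sites, "site(s),",
      paste(x$years, collapse = "-"), sprintf("(%s regime)\n", x$regime))
  cat(sprintf("  planted LSD sensitivity: %.2f days/degC (warm) vs %.2f (cool)\n",
              x$planted_sens_warm, x$planted_sens_cool))
  cat(sprintf("  trend %.3f degC/yr, preseason %d d, LSD noise %.1f d, seed %d\n",
              x$trend_per_year, x$preseason_len_true, x$noise_sd_lsd, x$seed))
  invisible(x)
}

# Per-site trend direction implied by the scenario regime.
# mixed: odd site indices warm, even cool. shift: odd sites warm-then-cool,
# even sites cool-then-warm.
site_trend_sign <- function(cfg, site_index) {
  switch(cfg$regime,
    warming = 1,
    cooling = -1,
    mixed   = if (site_index %% 2 == 1) 1 else -1,
    shift   = if (site_index %% 2 == 1) 1 else -1
  )
}

# Planted per-year temperature offsets (degC added to every day of that
# year). Trends start at zero in the first year so warming sites accumulate
# predominantly positive anomalies relative to the fixed climatology (and
# cooling sites negative ones). "shift" rises then falls (or the mirror).
trend_offsets <- function(cfg, site_index) {
  yrs <- seq.int(cfg$years[1], cfg$years[2])
  s <- site_trend_sign(cfg, site_index) * cfg$trend_per_year
  if (cfg$regime == "shift") {
    mid <- yrs[ceiling(length(yrs) / 2)]
    off <- ifelse(yrs <= mid, s * (yrs - yrs[1]),
                  s * (mid - yrs[1]) - s * (yrs - mid))
  } else {
    off <- s * (yrs - yrs[1])
  }
  stats::setNames(off, yrs)
}
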