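# Synthetic-data generator: coupled climate, greenness, senescence truth and
# autumn productivity for independent sites, fully seeded.

# Deterministic seasonal climatology of daily mean temperature (degC) as a
# function of day-of-year: peak in mid-July, mid-latitude amplitude.
seasonal_tmean <- function(d) {
  8 + 12 * cos(2 * pi * (d - 196) / 365.25)
}

seasonal_radiation <- function(d) {
  160 + 130 * cos(2 * pi * (d - 172) / 365.25)
}

seasonal_precip_mean <- function(d) {
  1.8 + 0.6 * cos(2 * pi * (d - 15) / 365.25)
}

# Marginal-variance-preserving AR(1) noise: innovations are scaled so the
# stationary SD equals `sd` whatever phi is.
ar1_noise <- function(n, phi, sd) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + e[i]
  x
}

# Offset between daily mean and minimum temperature, calibrated so the
# expected count of preseason days with Tmin < 0 equals cfg$frost_rate,
# averaging over the planted per-year trend offsets. Daily noise is Normal
# with marginal SD sigma, so E[frost days] = sum_d Phi((offset - mu_d)/sigma)
# (linearity of expectation; AR(1) dependence does not change the mean).
calibrate_tmin_offset <- function(cfg, offsets) {
  pre_doys <- seq.int(cfg$base_lsd - cfg$preseason_len_true + 1, cfg$base_lsd)
  mu <- outer(seasonal_tmean(pre_doys), offsets, `+`)  # days x years
  sigma <- cfg$temp_noise_sd
  if (cfg$frost_rate == 0) {
    return(min(mu) - 6 * sigma)
  }
  expected <- function(off) mean(colSums(stats::pnorm((off - mu) / sigma)))
  lo <- min(mu) - 8 * sigma
  hi <- max(mu) + 8 * sigma
  stats::uniroot(function(o) expected(o) - cfg$frost_rate, c(lo, hi),
                 tol = 1e-8)$root
}

#' Construct a climate series object
#'
#' @param id site/cell identifier.
#' @param dates complete daily calendar (`Date`).
#' @param tmean,tmin daily mean/minimum temperature, degrees C.
#' @param precip daily precipitation, mm/day.
#' @param radiation daily shortwave radiation, W/m^2.
#' @param spei data.frame with columns `year`, `month`, `spei` (monthly,
#'   three-month-scale standardized drought index).
#' @return an object of class `climate_series`.
#' @export
climate_series <- function(id, dates, tmean, tmin, precip, radiation, spei) {
  stopifnot(length(dates) == length(tmean), length(tmean) == length(tmin),
            length(tmin) == length(precip), length(precip) == length(radiation))
  if (any(diff(dates) != 1)) stop("climate calendar must be complete daily")
  structure(list(id = id, dates = dates, tmean = tmean, tmin = tmin,
                 precip = precip, radiation = radiation, spei = spei),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat("Daily climate series", sQuote(x$id), "covering",
      format(min(x$dates)), "to", format(max(x$dates)),
      sprintf("(%d days)\n", length(x$dates)))
  invisible(x)
}

#' Generate a daily climate series for one synthetic site
#'
#' Daily mean temperature is a seasonal sinusoid plus the regime's planted
#' linear trend plus AR(1) noise; minimum temperature is the mean minus a
#' fixed offset calibrated so the expected preseason frost-day count equals
#' `cfg$frost_rate`; precipitation (gamma) and radiation (seasonal with
#' noise) are independent; monthly SPEI is drawn around `cfg$spei_mean` and
#' truncated to \[-3, 3\]. The calendar is complete. Fully determined by
#' `cfg` (including its seed) and the site index.
#'
#' @param cfg a [scenario_config()].
#' @param site_index 1-based site number.
#' @return a [climate_series()].
#' @export
generate_climate <- function(cfg, site_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"))
  offsets <- trend_offsets(cfg, site_index)
  dates <- seq(as.Date(sprintf("%d-01-01", cfg$years[1])),
               as.Date(sprintf("%d-12-31", cfg$years[2])), by = "day")
  yr <- as.integer(format(dates, "%Y"))
  d <- doy(dates)
  base <- seasonal_tmean(d) + offsets[as.character(yr)]
  with_seed(derive_seed(cfg$seed, 101L, site_index), {
    tmean <- base + ar1_noise(length(dates), cfg$ar1_phi, cfg$temp_noise_sd)
    tmin <- tmean - calibrate_tmin_offset(cfg, offsets)
    pm <- seasonal_precip_mean(d)
    precip <- stats::rgamma(length(dates), shape = 0.6, scale = pm / 0.6)
    radiation <- pmax(5, seasonal_radiation(d) + stats::rnorm(length(dates), 0, 25))
    months <- expand.grid(month = 1:12, year = seq.int(cfg$years[1], cfg$years[2]))
    spei_val <- pmin(3, pmax(-3, stats::rnorm(nrow(months), cfg$spei_mean, 1)))
    spei <- data.frame(year = months$year, month = months$month, spei = spei_val)
    cs <- climate_series(paste0("site", site_index), dates, as.numeric(tmean),
                         as.numeric(tmin), precip, radiation, spei)
    attr(cs, "site_index") <- as.integer(site_index)
    cs
  })
}

#' Planted true senescence dates for one site
#'
#' The true LSD of year y is `base_lsd + s * dT_y + eps`, where `dT_y` is the
#' mean-temperature anomaly over the `preseason_len_true` days ending at
#' `base_lsd`, relative to the deterministic seasonal climatology, and `s`
#' switches between the planted warm- and cool-side sensitivities at zero
#' anomaly (piecewise-linear hinge). `eps ~ Normal(0, noise_sd_lsd)`.
#'
#' @param cfg a [scenario_config()].
#' @param climate a [climate_series()] spanning all scenario years (normally
#'   from [generate_climate()]).
#' @return data.frame with columns `year`, `lsd_true`, `delta_t`,
#'   `sens_applied`.
#' @export
generate_lsd_truth <- function(cfg, climate) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(climate, "climate_series"))
  site_index <- attr(climate, "site_index") %||% 1L
  years <- sort(unique(as.integer(format(climate$dates, "%Y"))))
  L <- cfg$preseason_len_true
  pre_doys <- seq.int(cfg$base_lsd - L + 1, cfg$base_lsd)
  ref <- mean(seasonal_tmean(pre_doys))
  with_seed(derive_seed(cfg$seed, 211L, site_index), {
    eps <- stats::rnorm(length(years), 0, cfg$noise_sd_lsd)
    rows <- lapply(seq_along(years), function(i) {
      y <- years[i]
      win <- date_from_doy(y, pre_doys)
      if (min(win) < min(climate$dates))
        stop(sprintf("preseason window of year %d extends before series start", y))
      tbar <- mean(climate$tmean[climate$dates %in% win])
      dT <- tbar - ref
      s <- if (dT > 0) cfg$planted_sens_warm else cfg$planted_sens_cool
      data.frame(year = y, lsd_true = cfg$base_lsd + s * dT + eps[i],
                 delta_t = dT, sens_applied = s)
    })
    do.call(rbind, rows)
  })
}

# Forward double-logistic greenness model (the same curve the extractor
# fits): y(t) = a + b * (1/(1+exp(c (t-d))) + 1/(1+exp(e (t-f)))) with c < 0
# (green-up) and e > 0 (senescence). Off-season level is a+b, summer plateau
# a+2b, so the half-amplitude decline crossing sits exactly at t = f.
double_logistic <- function(t, a, b, c, d, e, f) {
  a + b * (1 / (1 + exp(c * (t - d))) + 1 / (1 + exp(e * (t - f))))
}

#' Construct a vegetation-index series object
#'
#' @param id cell/site identifier.
#' @param dates observation dates (`Date`), strictly increasing.
#' @param values vegetation-index values.
#' @param snow logical snow/QC flag per observation.
#' @return an object of class `vi_series`.
#' @export
vi_series <- function(id, dates, values, snow = rep(FALSE, length(dates))) {
  stopifnot(length(dates) == length(values), length(values) == length(snow))
  if (any(diff(as.numeric(dates)) <= 0)) stop("vi_series dates must be strictly increasing")
  if (any(!is.finite(values[!snow]))) stop("unflagged vi values must be finite")
  structure(list(id = id, dates = dates, values = values, snow = snow),
            class = "vi_series")
}

#' @export
print.vi_series <- function(x, ...) {
  cat("Vegetation-index series", sQuote(x$id), "with", length(x$dates),
      "observations,", sum(x$snow), "snow-flagged\n")
  invisible(x)
}

#' Render a synthetic vegetation-index trajectory
#'
#' Samples the forward double-logistic curve on a regular sub-monthly grid,
#' one curve per year with its senescence inflection placed at that year's
#' true LSD, so the dynamic-threshold (half-amplitude) date of the noise-free
#' curve equals the planted truth. Adds Normal observation noise; winter
#' (Dec-Feb) observations are snow-flagged with probability `snow_prob` and
#' corrupted by a multiplicative U(0.1, 0.5) factor.
#'
#' @param truth data.frame from [generate_lsd_truth()] (columns `year`,
#'   `lsd_true`).
#' @param cfg a [scenario_config()].
#' @param site_index 1-based site number (seeds the noise stream).
#' @return a [vi_series()].
#' @export
render_vi_series <- function(truth, cfg, site_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"), is.data.frame(truth))
  with_seed(derive_seed(cfg$seed, 307L, site_index), {
    pieces <- lapply(seq_len(nrow(truth)), function(i) {
      y <- truth$year[i]
      t <- seq(1, 365, by = cfg$cadence_days)
      v <- double_logistic(t, cfg$vi_background, cfg$vi_amplitude,
                           cfg$vi_rate_up, cfg$vi_greenup_doy,
                           cfg$vi_rate_down, truth$lsd_true[i])
      data.frame(date = date_from_doy(y, t), value = v)
    })
    obs <- do.call(rbind, pieces)
    obs$value <- obs$value + stats::rnorm(nrow(obs), 0, cfg$noise_sd_ndvi)
    snow <- is_winter(obs$date) & stats::runif(nrow(obs)) < cfg$snow_prob
    obs$value[snow] <- obs$value[snow] * stats::runif(sum(snow), 0.1, 0.5)
    vs <- vi_series(paste0("site", site_index), obs$date, obs$value, snow)
    vs
  })
}

#' Render synthetic autumn productivity coupled to senescence timing
#'
#' Per-year autumn productivity (accumulated, g C m^-2) is
#' `baseline + gamma * (true LSD - base_lsd) + kappa * autumn-temperature
#' anomaly + noise`, so the planted LSD asymmetry propagates into the
#' productivity response to temperature. Also returns a daily GPP series
#' whose September-November sum equals the per-year value, for aggregation
#' tests.
#'
#' @param truth data.frame from [generate_lsd_truth()].
#' @param climate matching [climate_series()].
#' @param cfg a [scenario_config()].
#' @param site_index 1-based site number.
#' @return list with `records` (data.frame `year`, `value`, `source`) and
#'   `daily` (data.frame `date`, `gpp` in g C m^-2 day^-1).
#' @export
render_productivity <- function(truth, climate, cfg, site_index = 1L) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(climate, "climate_series"))
  aut_ref <- mean(seasonal_tmean(doy(climate$dates[is_autumn(climate$dates)][1:91])))
  with_seed(derive_seed(cfg$seed, 401L, site_index), {
    noise <- stats::rnorm(nrow(truth), 0, cfg$noise_sd_prod)
    vals <- vapply(seq_len(nrow(truth)), function(i) {
      y <- truth$year[i]
      sel <- is_autumn(climate$dates) &
        as.integer(format(climate$dates, "%Y")) == y
      tanom <- mean(climate$tmean[sel]) - aut_ref
      cfg$prod_baseline + cfg$prod_gamma * (truth$lsd_true[i] - cfg$base_lsd) +
        cfg$prod_temp_coef * tanom + noise[i]
    }, numeric(1))
    records <- data.frame(year = truth$year, value = vals, source = "gpp")
    # daily series: uniform over the 91 autumn days, small off-season baseline
    gpp <- rep(0.5, length(climate$dates))
    yr <- as.integer(format(climate$dates, "%Y"))
    for (i in seq_len(nrow(truth))) {
      sel <- is_autumn(climate$dates) & yr == truth$year[i]
      gpp[sel] <- vals[i] / sum(sel)
    }
    list(records = records,
         daily = data.frame(date = climate$dates, gpp = gpp))
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs all generator stages for every site and assembles the collections the
#' analysis pipeline consumes, plus the planted truth for assertions. Species
#' labels cycle through four common European broadleaf taxa; biomes cycle
#' through ENF/DBF/MF.
#'
#' @param cfg a [scenario_config()].
#' @return an object of class `synthetic_dataset`: list with `pheno`
#'   (in-situ-style records), `vi`, `climate`, `productivity`, `gpp_daily`,
#'   `sites` (id, lat, lon, biome, species) and `truth`.
#' @examples
#' ds <- generate_dataset(scenario_config(n_sites = 2, years = c(2000, 2019),
#'                                        seed = 7))
#' head(ds$truth)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  species_pool <- c("Fagus sylvatica", "Betula pendula",
                    "Quercus robur", "Aesculus hippocastanum")
  biome_pool <- c("ENF", "DBF", "MF")
  sites <- data.frame(
    site_id = paste0("site", seq_len(cfg$n_sites)),
    lat = 45 + ((seq_len(cfg$n_sites) - 1) * 7L) %% 20,
    lon = ((seq_len(cfg$n_sites) - 1) * 13L) %% 40 - 10,
    biome = biome_pool[(seq_len(cfg$n_sites) - 1) %% 3 + 1],
    species = species_pool[(seq_len(cfg$n_sites) - 1) %% 4 + 1],
    trend_sign = vapply(seq_len(cfg$n_sites), function(i) site_trend_sign(cfg, i),
                        numeric(1))
  )
  climate <- vi <- prod_rec <- gpp_daily <- truth_list <- vector("list", cfg$n_sites)
  for (i in seq_len(cfg$n_sites)) {
    cl <- generate_climate(cfg, i)
    tr <- generate_lsd_truth(cfg, cl)
    pv <- render_productivity(tr, cl, cfg, i)
    climate[[i]] <- cl
    vi[[i]] <- render_vi_series(tr, cfg, i)
    prod_rec[[i]] <- cbind(cell_id = sites$site_id[i], pv$records)
    gpp_daily[[i]] <- cbind(cell_id = sites$site_id[i], pv$daily)
    tr$site_id <- sites$site_id[i]
    tr$regime_planted <- if (sites$trend_sign[i] > 0) "warming" else "cooling"
    truth_list[[i]] <- tr
  }
  names(climate) <- names(vi) <- sites$site_id
  truth <- do.call(rbind, truth_list)
  pheno <- data.frame(
    site_id = truth$site_id,
    species = sites$species[match(truth$site_id, sites$site_id)],
    year = truth$year,
    lsd = as.integer(round_half_up(truth$lsd_true))
  )
  structure(list(cfg = cfg, sites = sites, pheno = pheno, vi = vi,
                 climate = climate,
                 productivity = do.call(rbind, prod_rec),
                 gpp_daily = do.call(rbind, gpp_daily),
                 truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$sites), "site(s),",
      paste(x$cfg$years, collapse = "-"), sprintf("(%s regime)\n", x$cfg$regime))
  cat("  ", nrow(x$pheno), "phenology records,",
      sum(vapply(x$vi, function(v) length(v$dates), numeric(1))),
      "VI observations\n")
  invisible(x)
}
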