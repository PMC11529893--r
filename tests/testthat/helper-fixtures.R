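# Programmatic fixtures shared across test files.

# A vi_series sampled from the forward double-logistic curve, noise-free.
make_curve_series <- function(year = 2000, cadence = 15, a = -0.15, b = 0.3,
                              c = -0.08, d = 120, e = 0.08, f = 280,
                              snow = NULL) {
  t <- seq(1, 365, by = cadence)
  v <- a + b * (1 / (1 + exp(c * (t - d))) + 1 / (1 + exp(e * (t - f))))
  if (is.null(snow)) snow <- rep(FALSE, length(t))
  vi_series("fix", date_from_doy(year, t), v, snow)
}

# A climate_series with fully specified daily values (recycled), constant
# unless overridden; spans the given years with a complete calendar.
make_climate <- function(years = c(2000, 2001), tmean = 10, tmin = NULL,
                         precip = 1, radiation = 100, spei_val = 0,
                         id = "fix") {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[2])), by = "day")
  n <- length(dates)
  tmean <- rep_len(tmean, n)
  if (is.null(tmin)) tmin <- tmean - 5
  months <- expand.grid(month = 1:12, year = seq.int(years[1], years[2]))
  spei <- data.frame(year = months$year, month = months$month,
                     spei = rep_len(spei_val, nrow(months)))
  climate_series(id, dates, tmean, rep_len(tmin, n), rep_len(precip, n),
                 rep_len(radiation, n), spei)
}

# Memoized pipeline run shared by the pipeline test blocks.
shared_pipeline <- local({
  cache <- new.env()
  function(config, out_dir = NULL) {
    key <- digest_key(config)
    if (is.null(cache[[key]])) cache[[key]] <- run_pipeline(config)
    if (!is.null(out_dir)) write_pipeline_result(cache[[key]], out_dir)
    cache[[key]]
  }
})

digest_key <- function(x) paste(deparse(x), collapse = "")

# A tiny scenario for generator tests.
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_sites = 1L, years = c(2000L, 2019L), seed = 42L,
                   noise_sd_ndvi = 0, snow_prob = 0, noise_sd_lsd = 0)
  do.call(scenario_config, utils::modifyList(defaults, args))
}
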