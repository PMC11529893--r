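# Propagation of senescence asymmetry into autumn productivity and the
# carbon-budget bias of ignoring it.

#' Aggregate autumn productivity for one cell-year
#'
#' kNDVI sources are averaged over September-November observations; GPP
#' sources are accumulated: each observation (a daily rate) is weighted by
#' the number of autumn days it covers, so 8-day or monthly composites are
#' apportioned by day overlap and daily data reduce to a plain sum.
#'
#' @param dates observation dates (`Date`).
#' @param values productivity values (kNDVI: dimensionless; GPP: g C m^-2
#'   day^-1 rates).
#' @param year calendar year.
#' @param source `"kndvi"` or `"gpp"`.
#' @return list matching one productivity record: `cell-year` value in the
#'   source's units (`year`, `autumn_value`, `source`).
#' @export
autumn_productivity <- function(dates, values, year, source = c("kndvi", "gpp")) {
  source <- match.arg(source)
  stopifnot(length(dates) == length(values))
  aut_start <- as.Date(sprintf("%d-09-01", year))
  aut_end <- as.Date(sprintf("%d-11-30", year))
  ord <- order(dates)
  dates <- dates[ord]; values <- values[ord]
  # coverage interval of each observation: from its date to the day before
  # the next observation (last one covers its own cadence)
  if (length(dates) > 1) {
    cad <- as.numeric(diff(dates))
    ends <- c(dates[-1] - 1, dates[length(dates)] + cad[length(cad)] - 1)
  } else {
    ends <- dates
  }
  cover <- pmax(0, as.numeric(pmin(ends, aut_end) - pmax(dates, aut_start)) + 1)
  in_autumn <- cover > 0
  if (!any(in_autumn)) stop(sprintf("no autumn observations in year %d", year))
  val <- if (source == "kndvi") {
    mean(values[dates >= aut_start & dates <= aut_end])
  } else {
    sum(values[in_autumn] * cover[in_autumn])
  }
  if (source == "kndvi" && is.nan(val))
    stop(sprintf("no autumn observations in year %d", year))
  list(year = year, autumn_value = val, source = source)
}

#' Temperature sensitivity of autumn productivity
#'
#' Same contract as [mlr_sensitivity()], with autumn productivity as the
#' response: multiple linear regression on autumn temperature, controlling
#' for precipitation and radiation. The slope is in productivity units per
#' degree C.
#'
#' @param values per-year autumn productivity.
#' @param covars data.frame with columns `temp`, `precip`, `rad` (autumn
#'   climate covariates per year).
#' @return a `sensitivity_result` (method `mlr`, `response = "productivity"`).
#' @export
productivity_sensitivity <- function(values, covars) {
  res <- mlr_sensitivity(values, covars)
  res$response <- "productivity"
  res
}

#' Coupling of senescence and productivity sensitivities
#'
#' OLS of per-cell productivity sensitivity on per-cell senescence
#' sensitivity (both to temperature), across cells.
#'
#' @param s_lsd per-cell LSD sensitivities (days/degC).
#' @param s_prod per-cell productivity sensitivities (units/degC).
#' @return list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
coupling_regression <- function(s_lsd, s_prod) {
  stopifnot(length(s_lsd) == length(s_prod))
  if (length(s_lsd) < 3) stop("need at least 3 cells")
  fit <- stats::lm(s_prod ~ s_lsd)
  sm <- suppressWarnings(summary(fit))  # exact coupling: perfect fit
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, "Pr(>|t|)"]),
       n = length(s_lsd))
}

#' Carbon-budget bias of ignoring asymmetric productivity responses
#'
#' Per biome, the bias of assuming a symmetric response to a `delta_T`
#' temperature change is `area x |warming response - cooling response| x
#' delta_T`; the total is the sum over biomes, reported in g C yr^-1 and
#' Pg C yr^-1 (1 Pg = 1e15 g). A signed breakdown is also kept.
#'
#' @param warm_response named per-biome productivity responses under
#'   warming, g C m^-2 yr^-1 degC^-1.
#' @param cool_response same, under cooling (same biome names).
#' @param area named per-biome forest area, m^2.
#' @param delta_T temperature change magnitude, degC (> 0).
#' @return list of class `bias_estimate`: `per_biome` (data.frame with
#'   `biome`, `area_m2`, `delta_response`, `bias_g`), `total_g`, `total_pg`,
#'   `delta_T`.
#' @export
carbon_bias <- function(warm_response, cool_response, area, delta_T = 1) {
  biomes <- names(area)
  if (is.null(biomes) || !setequal(biomes, names(warm_response)) ||
      !setequal(biomes, names(cool_response)))
    stop("warm_response, cool_response and area must share biome names")
  if (delta_T <= 0) stop("delta_T must be positive")
  dr <- warm_response[biomes] - cool_response[biomes]
  bias_g <- area[biomes] * abs(dr) * delta_T
  per <- data.frame(biome = biomes, area_m2 = unname(area[biomes]),
                    delta_response = unname(dr), bias_g = unname(bias_g))
  structure(list(per_biome = per, total_g = sum(bias_g),
                 total_pg = sum(bias_g) / 1e15, delta_T = delta_T),
            class = "bias_estimate")
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("Carbon-budget bias of ignoring asymmetry (delta T = %g degC):\n",
              x$delta_T))
  print(x$per_biome, row.names = FALSE)
  cat(sprintf("total: %.4g g C yr^-1 = %.4g Pg C yr^-1\n", x$total_g, x$total_pg))
  invisible(x)
}
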