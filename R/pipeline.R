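# End-to-end pipeline: synthetic grid -> senescence extraction -> climate
# metrics -> regimes and sensitivities -> asymmetry tests -> productivity
# link, with per-stage drop accounting and a machine-readable manifest.

pipeline_defaults <- function() {
  list(
    alpha = 0.05,
    preseason_grid = seq(8L, 120L, by = 8L),
    tbases = c(5, 10, 15),
    mad_k = 2.5,
    sg_window = 7L,
    sg_polyorder = 3L,
    mask_threshold = 0.1,
    lsd_threshold = 0.5,
    ridge_lambda = NULL,      # NULL: generalized cross-validation per unit
    n_boot = 1000L,
    regime_period = NULL,     # NULL: full scenario span
    window_years = 15L,
    biome_area = c(ENF = 1e12, DBF = 1e12, MF = 1e12),  # m^2
    delta_T = 1
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  logged <- character(0)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
      logged <- c(logged, nm)
    }
  }
  if (!is.null(config$biome_area)) config$biome_area <- unlist(config$biome_area)
  attr(config, "defaulted") <- logged
  config
}

stage_try <- function(stage, unit, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed at unit '%s': %s", stage, unit,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full asymmetry-analysis pipeline
#'
#' Generates (or accepts) a synthetic multi-site dataset, extracts annual
#' senescence dates from the greenness series, MAD-filters them, computes
#' climate metrics (cold-degree days, preseason statistics, frost risk),
#' classifies warming/cooling regimes from autumn temperature trends, selects
#' each unit's optimal preseason by partial correlation, estimates ridge and
#' multiple-linear-regression temperature sensitivities, tests the
#' warming-cooling asymmetry, and propagates it to autumn productivity and
#' the carbon-budget bias. Every record dropped by a filter is counted in
#' the manifest so that input count = output count + drops at each stage.
#'
#' @param config a named list or YAML file path. `scenario` holds
#'   [scenario_config()] arguments; other entries override analysis
#'   parameters (`alpha`, `preseason_grid`, `tbases`, `mad_k`, `sg_window`,
#'   `sg_polyorder`, `mask_threshold`, `lsd_threshold`, `ridge_lambda`,
#'   `n_boot`, `regime_period`, `window_years`, `biome_area`, `delta_T`);
#'   missing entries default to the standard values and are logged in the
#'   manifest.
#' @param out_dir output directory for result tables and the manifest;
#'   `NULL` skips writing.
#' @param dataset optionally a pre-built [generate_dataset()] result
#'   (overrides `config$scenario`).
#' @return list of class `pipeline_result` with `lsd`, `metrics`, `regimes`,
#'   `preseason`, `sensitivities`, `tests`, `productivity`, `coupling`,
#'   `bias`, `frost`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, dataset = NULL) {
  config <- read_pipeline_config(config)
  counts <- list()

  ## stage: synth
  if (is.null(dataset)) {
    cfg <- do.call(scenario_config, config$scenario %||% list())
    dataset <- stage_try("synth", "all", generate_dataset(cfg))
  }
  cfg <- dataset$cfg
  sites <- dataset$sites
  counts$sites_in <- nrow(sites)

  ## stage: extract
  lsd_rows <- list(); masked <- 0L; year_failures <- 0L; mad_removed <- 0L
  for (id in sites$site_id) {
    tab <- stage_try("extract", id,
      extract_lsd(dataset$vi[[id]], config$sg_window, config$sg_polyorder,
                  config$mask_threshold, config$lsd_threshold))
    if (is.null(tab)) { masked <- masked + 1L; next }
    bad <- is.na(tab$lsd)
    year_failures <- year_failures + sum(bad)
    tab <- tab[!bad, , drop = FALSE]
    if (nrow(tab) >= 3) {
      mf <- mad_filter(tab$lsd, config$mad_k)
      mad_removed <- mad_removed + length(mf$removed)
      tab <- tab[mf$kept, , drop = FALSE]
    }
    lsd_rows[[id]] <- tab
  }
  lsd <- do.call(rbind, lsd_rows)
  counts$cells_masked_sparse <- masked
  counts$year_extraction_failures <- year_failures
  counts$lsd_outliers_removed <- mad_removed
  counts$lsd_records <- nrow(lsd)

  ## stage: metrics (cold-degree days + autumn means per retained cell-year)
  metrics <- do.call(rbind, lapply(split(lsd, lsd$cell_id), function(tab) {
    cl <- dataset$climate[[tab$cell_id[1]]]
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      y <- tab$year[i]
      cdds <- vapply(config$tbases, function(tb)
        stage_try("metrics", tab$cell_id[1],
                  cdd_accumulate(cl, y, tab$lsd[i], tb)), numeric(1))
      out <- data.frame(cell_id = tab$cell_id[1], year = y, lsd = tab$lsd[i],
                        autumn_tmean = autumn_mean_temperature(cl, y))
      out[paste0("cdd", config$tbases)] <- as.list(cdds)
      out
    }))
  }))
  rownames(metrics) <- NULL

  ## stage: regimes
  regimes <- do.call(rbind, lapply(unique(lsd$cell_id), function(id) {
    rl <- stage_try("regimes", id,
                    classify_regime(dataset$climate[[id]],
                                    config$regime_period, config$alpha))
    data.frame(cell_id = id, regime = rl$regime, trend_slope = rl$trend_slope,
               trend_p = rl$trend_p)
  }))
  counts$cells_regime_none <- sum(regimes$regime == "none")

  ## stage: preseason + sensitivities
  sens_rows <- list(); pre_rows <- list(); excluded_preseason <- 0L
  analyzed <- regimes$cell_id[regimes$regime != "none"]
  for (id in analyzed) {
    tab <- lsd[lsd$cell_id == id, ]
    cl <- dataset$climate[[id]]
    pw <- stage_try("preseason", id,
      optimal_preseason(tab, cl, config$preseason_grid, config$alpha,
                        config$mad_k))
    pre_rows[[id]] <- data.frame(cell_id = id, length = pw$length,
                                 anchor = pw$anchor, partial_r = pw$r,
                                 partial_p = pw$p)
    if (is.na(pw$length)) { excluded_preseason <- excluded_preseason + 1L; next }
    st <- lapply(tab$year, function(y)
      preseason_stats(cl, pw$length, pw$anchor, y))
    covars <- data.frame(
      temp = vapply(st, `[[`, numeric(1), "tmean_mean"),
      precip = vapply(st, `[[`, numeric(1), "precip_sum"),
      rad = vapply(st, `[[`, numeric(1), "rad_mean"))
    mlr <- stage_try("sensitivity", id, mlr_sensitivity(tab$lsd, covars))
    ridge <- stage_try("sensitivity", id,
      ridge_sensitivity(tab$lsd, covars, lambda = config$ridge_lambda,
                        n_boot = config$n_boot,
                        boot_seed = derive_seed(cfg$seed, 503L,
                                                match(id, sites$site_id))))
    sens_rows[[id]] <- data.frame(
      cell_id = id,
      regime = regimes$regime[regimes$cell_id == id],
      biome = sites$biome[sites$site_id == id],
      preseason_length = pw$length,
      mlr_slope = mlr$slope, mlr_se = mlr$se, mlr_p = mlr$p,
      ridge_slope = ridge$slope, ridge_se = ridge$se,
      ridge_lambda = ridge$lambda,
      tstd = mean(vapply(st, `[[`, numeric(1), "tmean_sd")),
      frost_days = mean(vapply(st, `[[`, numeric(1), "frost_days")),
      spei_mean = mean(vapply(st, `[[`, numeric(1), "spei_mean")))
  }
  sens <- do.call(rbind, sens_rows)
  rownames(sens) <- NULL
  preseason <- do.call(rbind, pre_rows)
  counts$cells_excluded_no_preseason <- excluded_preseason
  counts$cells_with_sensitivity <- nrow(sens)

  ## stage: asymmetry tests
  tests <- list()
  both <- !is.null(sens) && all(c("warming", "cooling") %in% sens$regime) &&
    min(table(sens$regime)) >= 2
  if (both) {
    tests$mlr_t <- group_sensitivities(sens$mlr_slope, sens$regime)
    tests$ridge_t <- group_sensitivities(sens$ridge_slope, sens$regime)
    met <- merge(metrics, sens[, c("cell_id", "regime", "biome")], by = "cell_id")
    tests$lsd_cdd_ancova <- compare_slopes_ancova(met$cdd10, met$lsd, met$regime)
    tests$tstd_mixed <- mixed_compare(sens$tstd, sens$regime, sens$biome)
    tests$spei_mixed <- mixed_compare(sens$spei_mean, sens$regime, sens$biome)
    frost_idx <- frost_risk_index(sens$frost_days)
    tests$frost_mixed <- mixed_compare(frost_idx, sens$regime, sens$biome)
    frost_rel <- tryCatch(sensitivity_vs_frost(sens$ridge_slope, frost_idx),
                          error = function(e) NULL)
    sens$frost_index <- frost_idx
  } else {
    frost_rel <- NULL
  }

  ## stage: productivity
  prod_rows <- list()
  for (id in if (is.null(sens)) character(0) else sens$cell_id) {
    g <- dataset$gpp_daily[dataset$gpp_daily$cell_id == id, ]
    cl <- dataset$climate[[id]]
    yrs <- sort(unique(lsd$year[lsd$cell_id == id]))
    vals <- vapply(yrs, function(y)
      stage_try("productivity", id,
                autumn_productivity(g$date, g$gpp, y, "gpp"))$autumn_value,
      numeric(1))
    aut <- lapply(yrs, function(y) {
      span <- seq(as.Date(sprintf("%d-09-01", y)),
                  as.Date(sprintf("%d-11-30", y)), by = "day")
      sel <- as.integer(span - cl$dates[1]) + 1L
      list(temp = mean(cl$tmean[sel]), precip = sum(cl$precip[sel]),
           rad = mean(cl$radiation[sel]))
    })
    covars <- data.frame(temp = vapply(aut, `[[`, numeric(1), "temp"),
                         precip = vapply(aut, `[[`, numeric(1), "precip"),
                         rad = vapply(aut, `[[`, numeric(1), "rad"))
    ps <- stage_try("productivity", id, productivity_sensitivity(vals, covars))
    prod_rows[[id]] <- data.frame(
      cell_id = id, regime = sens$regime[sens$cell_id == id],
      biome = sens$biome[sens$cell_id == id],
      prod_slope = ps$slope, prod_se = ps$se, prod_p = ps$p)
  }
  prod <- do.call(rbind, prod_rows)
  rownames(prod) <- NULL

  coupling <- NULL; bias <- NULL
  if (!is.null(prod) && both) {
    tests$prod_t <- group_sensitivities(prod$prod_slope, prod$regime)
    coupling <- coupling_regression(sens$mlr_slope, prod$prod_slope)
    resp <- stats::aggregate(prod_slope ~ biome + regime, prod, mean)
    warm <- stats::setNames(resp$prod_slope[resp$regime == "warming"],
                            resp$biome[resp$regime == "warming"])
    cool <- stats::setNames(resp$prod_slope[resp$regime == "cooling"],
                            resp$biome[resp$regime == "cooling"])
    biomes <- intersect(names(warm), names(cool))
    biomes <- intersect(biomes, names(config$biome_area))
    counts$biomes_in_bias <- length(biomes)
    if (length(biomes) > 0) {
      bias <- carbon_bias(warm[biomes], cool[biomes],
                          config$biome_area[biomes], config$delta_T)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenoasym")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    scenario = unclass(cfg),
    parameters = config[setdiff(names(config), "scenario")],
    defaulted_parameters = attr(config, "defaulted"),
    counts = counts,
    stages_complete = c("synth", "extract", "metrics", "regimes",
                        "preseason", "sensitivity", "tests", "productivity")
  )

  result <- structure(list(lsd = lsd, metrics = metrics, regimes = regimes,
                           preseason = preseason, sensitivities = sens,
                           tests = tests, productivity = prod,
                           coupling = coupling, bias = bias,
                           frost = frost_rel, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", x$manifest$counts$sites_in, "site(s),",
      x$manifest$counts$lsd_records, "senescence records\n")
  if (!is.null(x$tests$mlr_t)) {
    m <- x$tests$mlr_t$means
    cat(sprintf("  LSD sensitivity (MLR): %.2f (warming) vs %.2f (cooling) days/degC, p = %.3g\n",
                m[1], m[2], x$tests$mlr_t$p))
  }
  if (!is.null(x$bias))
    cat(sprintf("  carbon bias: %.4g Pg C yr^-1\n", x$bias$total_pg))
  invisible(x)
}

#' Write pipeline result tables and manifest
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  wr(result$lsd, "lsd.csv")
  wr(result$metrics, "metrics.csv")
  wr(result$regimes, "regimes.csv")
  wr(result$preseason, "preseason.csv")
  wr(result$sensitivities, "sensitivities.csv")
  wr(result$productivity, "productivity_sensitivities.csv")
  tests_df <- do.call(rbind, lapply(names(result$tests), function(nm) {
    t <- result$tests[[nm]]
    data.frame(test = nm, method = t$method, statistic = t$statistic, p = t$p)
  }))
  wr(tests_df, "tests.csv")
  if (!is.null(result$bias)) wr(result$bias$per_biome, "carbon_bias.csv")
  extra <- list(coupling = result$coupling,
                bias_total_pg = if (!is.null(result$bias)) result$bias$total_pg,
                frost_relation = result$frost)
  jsonlite::write_json(c(result$manifest, extra),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
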