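# Readers and writers: delimited-text phenology records and long-format
# gridded stacks (cell_id, lat, lon, date, value).

#' Read in-situ phenology records
#'
#' Parses a delimited text file with header columns `site_id`, `species`,
#' `year`, `lsd` (day-of-year) and optional `lat`/`lon`. Rows with
#' unparsable or out-of-range senescence dates (outside 1-366) are dropped
#' with a warning reporting the count; duplicate (site, species, year) keys
#' are an error.
#'
#' @param path file path (comma- or tab-delimited, autodetected).
#' @param sep field separator; `NULL` autodetects comma vs tab.
#' @return data.frame of records; attribute `"n_dropped"` counts dropped
#'   rows.
#' @export
read_pheno_records <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("site_id", "species", "year", "lsd")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  lsd <- suppressWarnings(as.numeric(df$lsd))
  ok <- is.finite(lsd) & lsd >= 1 & lsd <= 366
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(sprintf("%d record(s) dropped for unparsable or out-of-range lsd", n_dropped))
  df <- df[ok, , drop = FALSE]
  df$lsd <- as.integer(lsd[ok])
  key <- paste(df$site_id, df$species, df$year, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (site, species, year) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Write phenology records
#'
#' @param df data.frame with at least `site_id`, `species`, `year`, `lsd`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_pheno_records <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a gridded stack as long-format delimited text
#'
#' One row per (cell, date): `cell_id, lat, lon, date, <variable>[, ...]`.
#'
#' @param cells data.frame with `cell_id`, `lat`, `lon` (one row per cell).
#' @param series named list (by cell_id) of data.frames with a `date`
#'   column plus value column(s).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_grid_stack <- function(cells, series, path) {
  rows <- lapply(cells$cell_id, function(id) {
    s <- series[[id]]
    cbind(cell_id = id,
          lat = cells$lat[cells$cell_id == id],
          lon = cells$lon[cells$cell_id == id], s)
  })
  out <- do.call(rbind, rows)
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded stack from long-format delimited text
#'
#' @param path CSV written in the layout of [write_grid_stack()].
#' @param variable name of the value column to extract.
#' @return list with `cells` (data.frame `cell_id`, `lat`, `lon`, `valid`)
#'   and `series` (named list of data.frames `date`, `value`, plus any
#'   remaining columns). A cell whose values are all missing is flagged
#'   `valid = FALSE`. Non-monotone per-cell time axes are an error.
#' @export
read_grid_stack <- function(path, variable) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("cell_id", "lat", "lon", "date"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  if (!variable %in% names(df)) stop("missing variable column: ", variable)
  df$date <- as.Date(df$date)
  ids <- unique(df$cell_id)
  series <- list()
  valid <- logical(length(ids))
  for (i in seq_along(ids)) {
    s <- df[df$cell_id == ids[i], , drop = FALSE]
    if (any(diff(as.numeric(s$date)) <= 0))
      stop("non-monotone time axis for cell ", ids[i])
    vals <- s[[variable]]
    valid[i] <- any(is.finite(vals))
    extra <- setdiff(names(s), c("cell_id", "lat", "lon", "date", variable))
    out <- data.frame(date = s$date, value = vals)
    for (col in extra) out[[col]] <- s[[col]]
    series[[ids[i]]] <- out
  }
  cells <- unique(df[, c("cell_id", "lat", "lon")])
  cells$valid <- valid[match(cells$cell_id, ids)]
  list(cells = cells, series = series)
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the pipeline reads: phenology records, long-format
#' VI / climate / productivity stacks, and a JSON truth file for test
#' assertions.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pheno_records(ds$pheno, file.path(dir, "pheno.csv"))
  vi_series_df <- lapply(ds$vi, function(v)
    data.frame(date = v$dates, ndvi = v$values, snow = as.integer(v$snow)))
  write_grid_stack(data.frame(cell_id = ds$sites$site_id, lat = ds$sites$lat,
                              lon = ds$sites$lon),
                   vi_series_df, file.path(dir, "vi.csv"))
  climate_df <- lapply(ds$climate, function(cl)
    data.frame(date = cl$dates, tmean = cl$tmean, tmin = cl$tmin,
               precip = cl$precip, radiation = cl$radiation))
  write_grid_stack(data.frame(cell_id = ds$sites$site_id, lat = ds$sites$lat,
                              lon = ds$sites$lon),
                   climate_df, file.path(dir, "climate.csv"))
  spei_df <- do.call(rbind, lapply(names(ds$climate), function(id)
    cbind(cell_id = id, ds$climate[[id]]$spei)))
  utils::write.csv(spei_df, file.path(dir, "spei.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$gpp_daily, file.path(dir, "gpp_daily.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$productivity, file.path(dir, "productivity.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
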