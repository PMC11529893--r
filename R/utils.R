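# Shared small helpers: calendar conversions, rounding, seed derivation.

#' Day of year of a calendar date
#'
#' 1-based convention: Jan 1 = 1. Leap years use the actual calendar length.
#'
#' @param dates a `Date` vector.
#' @return integer day-of-year values.
#' @export
doy <- function(dates) {
  as.integer(strftime(dates, "%j"))
}

#' Calendar date from year and day-of-year
#'
#' @param year calendar year (vectorised).
#' @param d 1-based day-of-year.
#' @return a `Date` vector.
#' @export
date_from_doy <- function(year, d) {
  as.Date(d - 1, origin = as.Date(sprintf("%d-01-01", year)))
}

#' Round half up to the nearest integer
#'
#' Reported senescence dates are rounded half-up (x.5 goes to x+1), unlike
#' base `round()`'s round-half-even.
#'
#' @param x numeric.
#' @return numeric of integer values.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Deterministically derive a 32-bit seed from a master seed, an operation
# salt and a unit index, so independent generator stages stay reproducible
# and decoupled.
derive_seed <- function(seed, salt, index = 0L) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271 +
    as.numeric(salt) * 69621 + as.numeric(index) * 16807
  as.integer(s %% 2147483629 + 1)
}

# Evaluate an expression with a temporary RNG state; restores the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Is the date in meteorological autumn (September-November)?
is_autumn <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m >= 9L & m <= 11L
}

# Is the date in meteorological winter (December-February)?
is_winter <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m == 12L | m <= 2L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
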