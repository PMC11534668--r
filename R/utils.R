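# Shared helpers: partial-date handling, rounding convention, seeded blocks.

#' Precision of a FAERS partial date
#'
#' FAERS date fields are integers with day (`YYYYMMDD`), month (`YYYYMM`) or
#' year (`YYYY`) precision; missing values stay missing. Dates are never
#' silently coerced to a finer precision: downstream steps decide what
#' precision they can use.
#'
#' @param x integer (or string-of-digits) vector of FAERS dates.
#' @return character vector in `c("day", "month", "year", NA)`.
#' @export
#' @examples
#' date_precision(c(20230105, 202301, 2023, NA))
date_precision <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  n <- nchar(x)
  out[!is.na(x) & n == 8] <- "day"
  out[!is.na(x) & n == 6] <- "month"
  out[!is.na(x) & n == 4] <- "year"
  out
}

#' Convert day-precision FAERS dates to Date
#'
#' Month- or year-precision values, missing values, and non-calendar values
#' (e.g. `20231399`) become `NA`.
#'
#' @param x integer vector of FAERS dates.
#' @return `Date` vector.
#' @export
faers_date_as_date <- function(x) {
  d <- rep(as.Date(NA), length(x))
  day <- !is.na(x) & date_precision(x) == "day"
  d[day] <- as.Date(as.character(x[day]), format = "%Y%m%d")
  d
}

is_valid_day_date <- function(x) {
  !is.na(faers_date_as_date(x))
}

faers_year <- function(x) {
  p <- date_precision(x)
  ifelse(is.na(p), NA_integer_, as.integer(substr(as.character(x), 1, 4)))
}

#' Round half up
#'
#' Rounds halves away from zero at the given number of decimals (`2.345` ->
#' `2.35`), unlike [base::round()]'s round-half-even. This is the convention
#' used for every percentage the package prints.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage with the package rounding convention
#'
#' `100 * count / denominator`, rounded half up to `digits` decimals. A zero
#' denominator yields `NA` rather than `Inf`.
#'
#' @param count,denominator numeric.
#' @param digits decimal places (default 2).
#' @return numeric vector.
#' @export
#' @examples
#' percent_half_up(6207, 19289) # 32.18
percent_half_up <- function(count, denominator, digits = 2) {
  x <- 100 * count / denominator
  x[is.nan(x) | is.infinite(x)] <- NA_real_
  round_half_up(x, digits)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalize a PT for dictionary matching: trim, collapse internal
# whitespace, case-fold. Original casing is preserved for display.
pt_normalize <- function(x) {
  str_to_lower(str_squish(x))
}

stopf <- function(fmt, ..., class = NULL) {
  abort(sprintf(fmt, ...), class = class)
}
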