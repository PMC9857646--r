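#' Bounded count series container
#'
#' A validated time series of counts on \code{{0, ..., n}}, stored as a tibble
#' with columns `t` (1-based time index) and `value`, carrying the structural
#' range limit `n` as an attribute. `n` is always explicit — it is never
#' inferred from \code{max(value)}, because the observed maximum may undershoot
#' the true range.
#'
#' @param values Integer vector of observations.
#' @param n Positive integer range limit.
#' @return A tibble of class `"count_series"` with columns `t`, `value` and
#'   attribute `n`.
#' @export
count_series <- function(values, n) {
  stopifnot(length(n) == 1, is.finite(n), n >= 1, n == round(n))
  values <- as.integer(values)
  bad <- which(is.na(values) | values < 0 | values > n)
  if (length(bad)) {
    stop(sprintf("values outside {0, ..., %d} at positions: %s", n,
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  out <- tibble::tibble(t = seq_along(values), value = values)
  attr(out, "n") <- as.integer(n)
  class(out) <- c("count_series", class(out))
  out
}

# pull the integer values + n out of whatever the user handed us
series_values <- function(series) {
  if (inherits(series, "count_series") || is.data.frame(series)) {
    stopifnot("value" %in% names(series))
    as.integer(series$value)
  } else {
    as.integer(series)
  }
}

series_n <- function(series, n = NULL) {
  if (is.null(n)) n <- attr(series, "n")
  if (is.null(n)) stop("range limit `n` must be supplied", call. = FALSE)
  as.integer(n)
}

#' Sample binomial index of dispersion of a series
#'
#' \code{n * s^2 / (xbar * (n - xbar))} with the sample mean and (unbiased)
#' sample variance. Values above 1 indicate extra-binomial variation.
#'
#' @param series A [count_series()] (or integer vector with `n` given).
#' @param n Range limit; taken from the series attribute when absent.
#' @return Scalar sample BID.
#' @export
sample_bid <- function(series, n = NULL) {
  x <- series_values(series)
  n <- series_n(series, n)
  m <- mean(x)
  n * stats::var(x) / (m * (n - m))
}

#' Read a bounded count series from disk
#'
#' Accepts either plain text (one integer per line, blank lines ignored) or a
#' single-column CSV with a header line (canonically `value`); the two parse
#' identically. Out-of-range or non-integer tokens raise an error naming the
#' offending line numbers.
#'
#' @param path File to read.
#' @param n Structural range limit for validation (always explicit).
#' @return A [count_series()] tibble.
#' @export
read_count_series <- function(path, n) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  lines <- lines[keep]
  if (!length(lines)) stop("empty series file: ", path, call. = FALSE)
  first <- trimws(lines[1])
  header <- suppressWarnings(is.na(as.numeric(first)))
  if (header) {
    lines <- lines[-1]
    keep <- keep[-1]
  }
  vals <- suppressWarnings(as.numeric(trimws(lines)))
  bad <- which(is.na(vals) | vals != round(vals))
  if (length(bad)) {
    stop(sprintf("non-integer tokens on line(s): %s",
                 paste(keep[bad], collapse = ", ")), call. = FALSE)
  }
  out_of_range <- which(vals < 0 | vals > n)
  if (length(out_of_range)) {
    stop(sprintf("values outside {0, ..., %d} on line(s): %s", n,
                 paste(keep[out_of_range], collapse = ", ")), call. = FALSE)
  }
  count_series(vals, n = n)
}

#' Write a bounded count series to disk
#'
#' @param series A [count_series()] tibble.
#' @param path Output file.
#' @param format `"csv"` (single `value` column with header) or `"txt"` (one
#'   integer per line).
#' @return `path`, invisibly.
#' @export
write_count_series <- function(series, path, format = c("csv", "txt")) {
  format <- match.arg(format)
  vals <- series_values(series)
  if (format == "csv") {
    writeLines(c("value", as.character(vals)), path)
  } else {
    writeLines(as.character(vals), path)
  }
  invisible(path)
}

#' Generate a packaged-style synthetic fixture series
#'
#' Reproducible simulated series for examples and tests. The default
#' `"rainy_days"` kind emulates the regime of a weekly-rainy-days record
#' (counts of rainy days per week): n = 7, T = 313, CMPBAR(1) parameters
#' \code{(theta1, theta2, nu) = (1.2313, 0.9547, 0.0995)} — a strongly
#' over-dispersed regime whose sample BID typically lands above 1. The
#' packaged copy under \code{inst/extdata/synthetic_rainy_days.csv} is this
#' generator at `seed = 20230107`; it is synthetic, not an observed record.
#'
#' @param kind Fixture family; currently `"rainy_days"`.
#' @param T Series length.
#' @param seed Integer seed; same seed, same series.
#' @param params Optional [cmpbar_params()] override.
#' @return A [count_series()] tibble; the generating parameters are attached
#'   as attribute `"params"`.
#' @export
generate_fixture <- function(kind = "rainy_days", T = 313, seed = 20230107,
                             params = NULL) {
  kind <- match.arg(kind)
  if (is.null(params)) {
    params <- cmpbar_params(n = 7, theta1 = 1.2313, theta2 = 0.9547, nu = 0.0995)
  }
  out <- cmpbar_simulate(params, T = T, init = "stationary", seed = seed)
  attr(out, "params") <- params
  out
}
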