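#' Exchangeable CMPB thinning operator
#'
#' The CMPB thinning of a count `x` is the sum of `x` exchangeable, dependent
#' Bernoulli components whose joint law is the CMPB counting distribution, so
#' conditionally on its argument the operator is distributed
#' \code{CMPB(x, alpha, nu)} with \code{theta = alpha/(1 - alpha)}. Thinning
#' an empty set returns 0.
#'
#' @param x Non-negative integer count to thin.
#' @param theta Positive odds parameter of the counting series.
#' @param nu Dispersion exponent of the counting series.
#' @param size Number of independent thinnings of the same `x` to draw.
#' @param seed Optional integer seed (local RNG state).
#' @return Integer vector of length `size`, values in \code{{0,...,x}}.
#' @export
cmpb_thin <- function(x, theta, nu, size = 1, seed = NULL) {
  stopifnot(length(x) == 1, x >= 0, x == round(x))
  if (!is.null(seed)) return(withr::with_seed(seed, cmpb_thin(x, theta, nu, size)))
  if (x == 0) return(integer(size))
  rcmpb(size, cmpb(n = x, theta = theta, nu = nu))
}

#' Classical binomial thinning operator
#'
#' Each of the `x` units survives independently with probability `alpha`, so
#' the result is a \code{Binomial(x, alpha)} draw. This is the counting
#' operator underlying the classical binomial AR(1) competitor model.
#'
#' @param x Non-negative integer count to thin.
#' @param alpha Survival probability in \[0, 1\].
#' @param size Number of independent thinnings to draw.
#' @param seed Optional integer seed (local RNG state).
#' @return Integer vector of length `size`, values in \code{{0,...,x}}.
#' @export
binomial_thin <- function(x, alpha, size = 1, seed = NULL) {
  stopifnot(length(x) == 1, x >= 0, x == round(x))
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) return(withr::with_seed(seed, binomial_thin(x, alpha, size)))
  stats::rbinom(size, size = x, prob = alpha)
}

#' Sample the exchangeable Bernoulli counting vector itself
#'
#' Draws the full configuration \code{(Z_1, ..., Z_x)} behind one CMPB
#' thinning: the total is drawn from \code{CMPB(x, alpha, nu)} and the ones
#' are then placed uniformly at random among the `x` slots, which is exactly
#' the exchangeable joint law (it depends on the configuration only through
#' its sum). Mainly useful for checking pairwise-exchangeability properties.
#'
#' @inheritParams cmpb_thin
#' @return Integer 0/1 vector of length `x` (length 0 when `x = 0`).
#' @export
cmpb_thin_vector <- function(x, theta, nu, seed = NULL) {
  stopifnot(length(x) == 1, x >= 0, x == round(x))
  if (!is.null(seed)) return(withr::with_seed(seed, cmpb_thin_vector(x, theta, nu)))
  if (x == 0) return(integer(0))
  total <- rcmpb(1, cmpb(n = x, theta = theta, nu = nu))
  z <- integer(x)
  if (total > 0) z[sample.int(x, total)] <- 1L
  z
}
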