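#' The Conway-Maxwell-Poisson-binomial (CMPB) distribution
#'
#' A random variable on \code{{0, ..., n}} follows the CMPB distribution when
#' its pmf is proportional to \code{choose(n, x)^nu * theta^x}. The odds
#' parameter \code{theta = alpha / (1 - alpha)} tilts the location; the
#' dispersion exponent \code{nu} tilts the shape: \code{nu = 1} recovers the
#' binomial with success probability \code{alpha}, \code{nu = 0} a truncated
#' geometric-type power series, \code{nu < 1} over-dispersion and
#' \code{nu > 1} under-dispersion relative to the binomial benchmark.
#'
#' `cmpb()` builds a validated parameter specification. Exactly one of
#' `theta`, `alpha` or `lambda` must be supplied; `alpha` maps to
#' `theta = alpha/(1 - alpha)` and `lambda` (defined for `nu != 0`) to
#' `theta = lambda^nu`.
#'
#' @param n Positive integer, the predetermined upper limit of the range.
#' @param theta Positive finite real, the odds parameter.
#' @param nu Finite real dispersion exponent.
#' @param alpha Success-probability parameterization, in (0, 1).
#' @param lambda Rate parameterization, positive; requires `nu != 0`.
#'
#' @return An object of class `"cmpb"`: a list with elements `n`, `theta`,
#'   `nu`, plus derived `alpha` (and `lambda` when `nu != 0`).
#'
#' @examples
#' spec <- cmpb(n = 7, theta = 1.5, nu = 0.5)
#' dcmpb(0:7, spec)
#' cmpb_moments(spec)
#' cmpb_bid(spec)
#' @export
cmpb <- function(n, theta = NULL, nu, alpha = NULL, lambda = NULL) {
  stopifnot(length(n) == 1, is.numeric(n), is.finite(n), n >= 1, n == round(n))
  stopifnot(length(nu) == 1, is.numeric(nu), is.finite(nu))
  given <- c(theta = !is.null(theta), alpha = !is.null(alpha),
             lambda = !is.null(lambda))
  if (sum(given) != 1L) {
    stop("supply exactly one of `theta`, `alpha`, `lambda`", call. = FALSE)
  }
  if (!is.null(alpha)) {
    stopifnot(length(alpha) == 1, is.finite(alpha), alpha > 0, alpha < 1)
    theta <- alpha / (1 - alpha)
  }
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 1, is.finite(lambda), lambda > 0)
    if (nu == 0) stop("`lambda` is only defined for nu != 0", call. = FALSE)
    theta <- lambda^nu
  }
  stopifnot(length(theta) == 1, is.numeric(theta), is.finite(theta), theta > 0)
  out <- list(n = as.integer(n), theta = as.numeric(theta), nu = as.numeric(nu),
              alpha = theta / (1 + theta))
  if (nu != 0) out$lambda <- theta^(1 / nu)
  structure(out, class = "cmpb")
}

#' @export
print.cmpb <- function(x, ...) {
  cat(sprintf("CMPB(n = %d, theta = %.6g, nu = %.6g)  [alpha = %.6g]\n",
              x$n, x$theta, x$nu, x$alpha))
  invisible(x)
}

# log(sum(exp(v))) without overflow; -Inf-safe
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# log pmf vector of CMPB(n, theta, nu) for x = 0..n; n = 0 allowed (point
# mass at 0) so thinning of an empty set and l = 0 transition rows fall out.
cmpb_logpmf_vec <- function(n, theta, nu) {
  if (n == 0) return(0)
  x <- 0:n
  terms <- nu * lchoose(n, x) + x * log(theta)
  terms - logsumexp(terms)
}

cmpb_pmf_vec <- function(n, theta, nu) exp(cmpb_logpmf_vec(n, theta, nu))

#' Log normalizing constant of the CMPB distribution
#'
#' Computes \code{log S(theta, nu)} with
#' \code{S(theta, nu) = sum_x choose(n, x)^nu * theta^x}, evaluated in the log
#' domain by log-sum-exp so it is finite for any valid specification (large
#' `n` or extreme `nu` would overflow a naive term-by-term sum).
#'
#' @param spec A [cmpb()] specification.
#' @return The scalar \code{log S(theta, nu)}.
#' @export
cmpb_log_normalizer <- function(spec) {
  stopifnot(inherits(spec, "cmpb"))
  x <- 0:spec$n
  logsumexp(spec$nu * lchoose(spec$n, x) + x * log(spec$theta))
}

#' CMPB probability mass function
#'
#' @param x Integer vector of quantiles; values outside \code{{0,...,n}} are
#'   an error (the support is structural, not a tail).
#' @param spec A [cmpb()] specification.
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities, one per element of `x`.
#' @seealso [cmpb_pmf()] for the full probability table as a tibble.
#' @export
dcmpb <- function(x, spec, log = FALSE) {
  stopifnot(inherits(spec, "cmpb"))
  if (any(x != round(x)) || any(x < 0) || any(x > spec$n)) {
    stop("`x` must be integers in {0, ..., n}", call. = FALSE)
  }
  lp <- cmpb_logpmf_vec(spec$n, spec$theta, spec$nu)[x + 1L]
  if (log) lp else exp(lp)
}

#' CMPB cumulative distribution function
#'
#' @inheritParams dcmpb
#' @return \code{P(X <= x)} for each element of `x`.
#' @export
pcmpb <- function(x, spec) {
  stopifnot(inherits(spec, "cmpb"))
  if (any(x != round(x)) || any(x < 0) || any(x > spec$n)) {
    stop("`x` must be integers in {0, ..., n}", call. = FALSE)
  }
  cumsum(cmpb_pmf_vec(spec$n, spec$theta, spec$nu))[x + 1L]
}

#' Full CMPB probability table
#'
#' @param spec A [cmpb()] specification.
#' @return A tibble with columns `x` (0..n) and `prob`, summing to 1.
#' @export
cmpb_pmf <- function(spec) {
  stopifnot(inherits(spec, "cmpb"))
  tibble::tibble(x = 0:spec$n,
                 prob = cmpb_pmf_vec(spec$n, spec$theta, spec$nu))
}

# mean/variance from an exact pmf vector on 0..(length-1)
pmf_moments <- function(p) {
  x <- seq_along(p) - 1
  mu <- sum(x * p)
  list(mean = mu, variance = sum(x^2 * p) - mu^2)
}

#' Mean and variance of a CMPB distribution
#'
#' The default route sums over the exact length-(n+1) probability vector. The
#' analytic route evaluates the power-series derivatives: with
#' \code{S' = dS/dtheta}, \code{E(X) = theta S'/S} and
#' \code{Var(X) = theta S'/S + theta^2 (S''/S - (S'/S)^2)}. The two are
#' algebraically identical; both are exposed so they can cross-check each
#' other.
#'
#' @param spec A [cmpb()] specification.
#' @param method `"pmf"` (exact probability vector, default) or `"series"`
#'   (termwise derivatives of S in the log domain).
#' @return A tibble with columns `mean` and `variance`.
#' @export
cmpb_moments <- function(spec, method = c("pmf", "series")) {
  stopifnot(inherits(spec, "cmpb"))
  method <- match.arg(method)
  if (method == "pmf") {
    m <- pmf_moments(cmpb_pmf_vec(spec$n, spec$theta, spec$nu))
  } else {
    n <- spec$n; th <- spec$theta; nu <- spec$nu
    x <- 0:n
    lt <- nu * lchoose(n, x) + x * log(th)          # log theta^x C^nu
    lS <- logsumexp(lt)
    # theta*S'/S = sum x p_x; theta^2*S''/S = sum x(x-1) p_x, in log domain
    pos <- x >= 1
    EthSp <- exp(logsumexp(lt[pos] + log(x[pos])) - lS)
    pos2 <- x >= 2
    Eth2Spp <- if (any(pos2)) {
      exp(logsumexp(lt[pos2] + log(x[pos2]) + log(x[pos2] - 1)) - lS)
    } else 0
    m <- list(mean = EthSp, variance = EthSp + Eth2Spp - EthSp^2)
  }
  tibble::tibble(mean = m$mean, variance = m$variance)
}

#' Binomial index of dispersion of a CMPB distribution
#'
#' \code{BID = n Var(X) / (E(X) (n - E(X)))}: 1 for the binomial, above 1
#' over-dispersed, below 1 under-dispersed. For the CMPB law the regime is
#' governed by `nu`: \code{nu < 1} gives BID >= 1, \code{nu = 1} exactly 1,
#' \code{nu > 1} BID <= 1.
#'
#' @param spec A [cmpb()] specification.
#' @return The scalar BID.
#' @export
cmpb_bid <- function(spec) {
  m <- cmpb_moments(spec)
  spec$n * m$variance / (m$mean * (spec$n - m$mean))
}

#' Sample from a CMPB distribution
#'
#' Inverse-cdf sampling: the probability ladder starts at \code{P(X = 0)} and
#' climbs through the one-term recurrence
#' \code{P(X = x + 1) = ((n - x)/(x + 1))^nu * theta * P(X = x)}, accumulating
#' the cdf until the uniform draw is passed. The cdf is clamped to 1 at
#' \code{x = n} (rounding can leave it at 1 - 1e-16). Accumulation is in the
#' probability domain: the support is short and P(X = 0) is computed stably in
#' the log domain first.
#'
#' @param m Number of draws.
#' @param spec A [cmpb()] specification.
#' @param seed Optional integer; when supplied the draws are produced under a
#'   local RNG state so the caller's stream is untouched.
#' @return Integer vector of length `m` with values in \code{{0,...,n}}.
#' @export
rcmpb <- function(m, spec, seed = NULL) {
  stopifnot(inherits(spec, "cmpb"), m >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, rcmpb(m, spec)))
  }
  n <- spec$n; theta <- spec$theta; nu <- spec$nu
  # cdf by the recurrence, starting from the log-domain P(X = 0)
  p <- exp(-cmpb_log_normalizer(spec))  # C(n,0)^nu theta^0 / S
  cdf <- numeric(n + 1)
  cdf[1] <- p
  if (n >= 1) {
    for (x in 0:(n - 1)) {
      p <- p * ((n - x) / (x + 1))^nu * theta
      cdf[x + 2] <- cdf[x + 1] + p
    }
  }
  cdf[n + 1] <- 1
  u <- stats::runif(m)
  # smallest x with u < F(x)
  as.integer(findInterval(u, cdf, left.open = FALSE))
}

#' Joint pmf of the exchangeable Bernoulli counting vector
#'
#' The CMPB law is the distribution of a sum of `n` exchangeable, dependent
#' Bernoulli components \code{Z_1, ..., Z_n} with joint pmf
#' \code{P(z) = choose(n, x)^(nu - 1) theta^x / S(theta, nu)} where
#' \code{x = sum(z)}. The probability depends on `z` only through its sum, so
#' any permutation of `z` has identical probability (exchangeability), and
#' marginalizing over the \code{choose(n, x)} arrangements with sum `x`
#' recovers the CMPB pmf at `x`.
#'
#' @param z Binary vector of length `n`.
#' @param spec A [cmpb()] specification with matching `n`.
#' @param log Return the log probability?
#' @return Scalar (log) probability of the configuration `z`.
#' @export
dcmpb_joint <- function(z, spec, log = FALSE) {
  stopifnot(inherits(spec, "cmpb"))
  if (length(z) != spec$n || !all(z %in% c(0, 1))) {
    stop("`z` must be a binary vector of length n", call. = FALSE)
  }
  x <- sum(z)
  lp <- (spec$nu - 1) * lchoose(spec$n, x) + x * log(spec$theta) -
    cmpb_log_normalizer(spec)
  if (log) lp else exp(lp)
}
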