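#' CMPBAR(1) model parameters
#'
#' The CMPBAR(1) process on \code{{0, ..., n}} is
#' \deqn{X_t = \alpha \diamond_\nu X_{t-1} + \beta \diamond_\nu (n - X_{t-1}),}
#' two independent exchangeable CMPB thinnings: survivors among the
#' \code{X_{t-1}} units in state 1 (survival odds
#' \code{theta1 = alpha/(1 - alpha)}) plus revivals among the
#' \code{n - X_{t-1}} units in state 0 (revival odds
#' \code{theta2 = beta/(1 - beta)}), sharing the dispersion exponent `nu`.
#' `nu = 1` collapses the model to the classical binomial AR(1).
#'
#' @param n Positive integer range limit.
#' @param theta1,theta2 Positive survival/revival odds. Alternatively supply
#'   `alpha`/`beta` probabilities in (0, 1).
#' @param nu Finite dispersion exponent shared by both thinnings.
#' @param alpha,beta Probability-scale parameterization.
#' @return An object of class `"cmpbar_params"`.
#' @examples
#' p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 0.25, nu = 0.5)
#' cmpbar_stationary_bid(p)  # > 1: over-dispersed regime
#' @export
cmpbar_params <- function(n, theta1 = NULL, theta2 = NULL, nu,
                          alpha = NULL, beta = NULL) {
  stopifnot(length(n) == 1, is.finite(n), n >= 1, n == round(n))
  stopifnot(length(nu) == 1, is.finite(nu))
  if (!is.null(alpha)) {
    stopifnot(is.finite(alpha), alpha > 0, alpha < 1)
    theta1 <- alpha / (1 - alpha)
  }
  if (!is.null(beta)) {
    stopifnot(is.finite(beta), beta > 0, beta < 1)
    theta2 <- beta / (1 - beta)
  }
  stopifnot(is.numeric(theta1), is.finite(theta1), theta1 > 0,
            is.numeric(theta2), is.finite(theta2), theta2 > 0)
  structure(list(n = as.integer(n), theta1 = as.numeric(theta1),
                 theta2 = as.numeric(theta2), nu = as.numeric(nu),
                 alpha = theta1 / (1 + theta1), beta = theta2 / (1 + theta2)),
            class = "cmpbar_params")
}

#' @export
print.cmpbar_params <- function(x, ...) {
  cat(sprintf(
    "CMPBAR(1) parameters: n = %d, theta1 = %.6g, theta2 = %.6g, nu = %.6g\n",
    x$n, x$theta1, x$theta2, x$nu))
  cat(sprintf("  (alpha = %.6g, beta = %.6g)\n", x$alpha, x$beta))
  invisible(x)
}

#' One-step transition probability of the CMPBAR(1) chain
#'
#' Direct evaluation of
#' \deqn{P(X_t = k \mid X_{t-1} = l) = \frac{1}{S(\theta_1,\nu) S(\theta_2,\nu)}
#'   \sum_i \binom{l}{i}^\nu \binom{n-l}{k-i}^\nu \theta_1^i \theta_2^{k-i},}
#' with the sum restricted to \code{max(0, k - (n - l)) <= i <= min(k, l)} so
#' that terms whose binomial coefficient vanishes are excluded rather than
#' exponentiated (for \code{nu <= 0} they would be \code{0^nu}). Each term is
#' evaluated in the log domain and combined by log-sum-exp.
#'
#' [cmpbar_transition_matrix()] assembles all rows at once via the equivalent
#' convolution of the two CMPB component pmfs; the two routes agree to
#' rounding and serve as mutual checks.
#'
#' @param params A [cmpbar_params()] object.
#' @param from Previous state `l` in \code{{0,...,n}}.
#' @param to Current state `k` in \code{{0,...,n}}.
#' @param log Return the log probability?
#' @return Scalar (log) transition probability.
#' @export
cmpbar_transition <- function(params, from, to, log = FALSE) {
  stopifnot(inherits(params, "cmpbar_params"))
  n <- params$n
  if (from < 0 || from > n || from != round(from) ||
      to < 0 || to > n || to != round(to)) {
    stop("`from` and `to` must be integers in {0, ..., n}", call. = FALSE)
  }
  l <- from; k <- to
  i <- seq.int(max(0, k - (n - l)), min(k, l))
  lterms <- params$nu * (lchoose(l, i) + lchoose(n - l, k - i)) +
    i * log(params$theta1) + (k - i) * log(params$theta2)
  lS1 <- logsumexp(params$nu * lchoose(l, 0:l) + (0:l) * log(params$theta1))
  lS2 <- logsumexp(params$nu * lchoose(n - l, 0:(n - l)) +
                     (0:(n - l)) * log(params$theta2))
  lp <- logsumexp(lterms) - lS1 - lS2
  if (log) lp else exp(lp)
}

# open (full) convolution of two probability vectors on 0..(la-1), 0..(lb-1)
conv_open <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Full transition matrix of the CMPBAR(1) chain
#'
#' Row `l` is the convolution of the \code{CMPB(l, theta1, nu)} and
#' \code{CMPB(n - l, theta2, nu)} component pmfs — the two independent
#' thinnings that make up one step. Every entry is strictly positive, which is
#' what makes the chain irreducible and aperiodic on \code{{0,...,n}} and
#' hence ergodic with a unique stationary law.
#'
#' @param params A [cmpbar_params()] object.
#' @return An \code{(n+1) x (n+1)} row-stochastic matrix; rows index the
#'   previous state `l = 0..n`, columns the next state `k = 0..n`.
#' @export
cmpbar_transition_matrix <- function(params) {
  stopifnot(inherits(params, "cmpbar_params"))
  n <- params$n
  P <- matrix(0, n + 1, n + 1, dimnames = list(from = 0:n, to = 0:n))
  for (l in 0:n) {
    p1 <- cmpb_pmf_vec(l, params$theta1, params$nu)
    p2 <- cmpb_pmf_vec(n - l, params$theta2, params$nu)
    P[l + 1, ] <- conv_open(p1, p2)
  }
  P
}

#' Exact stationary distribution of the CMPBAR(1) chain
#'
#' The chain is a finite irreducible aperiodic Markov chain, so the stationary
#' law is the unique probability vector solving \code{pi P = pi}; it is
#' computed exactly by a dense linear solve with the normalization constraint
#' appended. For `nu = 1` it reduces to
#' \code{Binomial(n, beta / (1 - alpha + beta))}, the classical binomial AR(1)
#' marginal.
#'
#' @param params A [cmpbar_params()] object.
#' @return A tibble with columns `x` (0..n) and `prob` (strictly positive,
#'   summing to 1).
#' @export
cmpbar_stationary <- function(params) {
  tibble::tibble(x = 0:params$n, prob = cmpbar_stationary_vec(params))
}

cmpbar_stationary_vec <- function(params) {
  P <- cmpbar_transition_matrix(params)
  m <- nrow(P)
  A <- rbind(t(P) - diag(m), rep(1, m))
  b <- c(numeric(m), 1)
  pi_hat <- unname(qr.solve(A, b))
  pi_hat / sum(pi_hat)
}

#' Simulate a CMPBAR(1) path
#'
#' Each step draws the two independent thinnings of the generative equation:
#' survivors \code{CMPB(X_{t-1}, theta1, nu)} plus revivals
#' \code{CMPB(n - X_{t-1}, theta2, nu)}. The per-state inverse cdfs of both
#' components are precomputed once, so long paths are cheap.
#'
#' By default the chain starts from an exact stationary draw with no burn-in;
#' with an explicit integer `init`, `burnin` steps (default 500) are discarded
#' first.
#'
#' @param params A [cmpbar_params()] object.
#' @param T Number of observations returned (the series is \code{X_1..X_T}
#'   after initialization; with a stationary start \code{X_0} is the
#'   stationary draw).
#' @param init `"stationary"` (default) or an integer starting state in
#'   \code{{0,...,n}}.
#' @param burnin Steps discarded after an explicit integer start; ignored for
#'   a stationary start.
#' @param seed Optional integer seed (local RNG state).
#' @return A [count_series()] tibble with columns `t` and `value`.
#' @export
cmpbar_simulate <- function(params, T, init = "stationary",
                            burnin = if (identical(init, "stationary")) 0 else 500,
                            seed = NULL) {
  stopifnot(inherits(params, "cmpbar_params"), T >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, cmpbar_simulate(params, T, init, burnin)))
  }
  n <- params$n
  # per-state inverse cdfs of the two thinning components
  cdf1 <- lapply(0:n, function(l) cumsum(cmpb_pmf_vec(l, params$theta1, params$nu)))
  cdf2 <- lapply(0:n, function(l) cumsum(cmpb_pmf_vec(l, params$theta2, params$nu)))
  if (identical(init, "stationary")) {
    pi0 <- cmpbar_stationary_vec(params)
    x <- findInterval(stats::runif(1), cumsum(pi0)) # value in 0..n
    x <- min(x, n)
  } else {
    if (length(init) != 1 || init != round(init) || init < 0 || init > n) {
      stop("`init` must be \"stationary\" or an integer in {0, ..., n}",
           call. = FALSE)
    }
    x <- as.integer(init)
  }
  total <- burnin + T
  u1 <- stats::runif(total)
  u2 <- stats::runif(total)
  out <- integer(total)
  for (t in seq_len(total)) {
    surv <- findInterval(u1[t], cdf1[[x + 1L]])        # thin X_{t-1}
    rev_ <- findInterval(u2[t], cdf2[[n - x + 1L]])    # thin n - X_{t-1}
    x <- min(surv, x) + min(rev_, n - x)               # clamp fp edge cases
    out[t] <- x
  }
  count_series(out[(burnin + 1):total], n = n)
}

#' Conditional mean and variance given the previous state
#'
#' Given \code{X_{t-1} = l}, the next value is the sum of two independent CMPB
#' components built on `l` and `n - l` units, so the conditional mean and
#' variance are the sums of the component moments
#' (\code{theta1 S1'/S1 + theta2 S2'/S2} and the matching variance sum). They
#' agree with the moments of the corresponding transition-matrix row.
#'
#' @param params A [cmpbar_params()] object.
#' @param from Integer vector of previous states in \code{{0,...,n}}.
#' @return A tibble with columns `from`, `mean`, `variance`.
#' @export
cmpbar_conditional_moments <- function(params, from = 0:params$n) {
  stopifnot(inherits(params, "cmpbar_params"))
  if (any(from < 0 | from > params$n | from != round(from))) {
    stop("`from` must be integers in {0, ..., n}", call. = FALSE)
  }
  one <- function(l) {
    m1 <- pmf_moments(cmpb_pmf_vec(l, params$theta1, params$nu))
    m2 <- pmf_moments(cmpb_pmf_vec(params$n - l, params$theta2, params$nu))
    c(mean = m1$mean + m2$mean, variance = m1$variance + m2$variance)
  }
  m <- vapply(from, one, c(mean = 0, variance = 0))
  tibble::tibble(from = as.integer(from),
                 mean = as.numeric(m["mean", ]),
                 variance = as.numeric(m["variance", ]))
}

#' Conditional binomial index of dispersion (CBID)
#'
#' The BID of the one-step conditional law \code{X_t | X_{t-1} = l}:
#' \code{n Var(X_t|l) / (E(X_t|l) (n - E(X_t|l)))}.
#'
#' @inheritParams cmpbar_conditional_moments
#' @return Numeric vector of CBID values, one per element of `from`.
#' @export
cmpbar_cbid <- function(params, from = 0:params$n) {
  m <- cmpbar_conditional_moments(params, from)
  params$n * m$variance / (m$mean * (params$n - m$mean))
}

#' Stationary binomial index of dispersion
#'
#' The BID of the exact stationary distribution. The marginal law has no
#' closed form, but the stationary vector of the finite chain is exact, so the
#' BID is computed from it directly rather than estimated from a simulated
#' path. Regimes: \code{nu < 1} over-dispersed (> 1), \code{nu = 1} exactly 1,
#' \code{nu > 1} under-dispersed (< 1).
#'
#' @param params A [cmpbar_params()] object.
#' @return The scalar stationary BID.
#' @export
cmpbar_stationary_bid <- function(params) {
  m <- pmf_moments(cmpbar_stationary_vec(params))
  params$n * m$variance / (m$mean * (params$n - m$mean))
}
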