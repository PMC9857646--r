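#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# transition-pair counts N[l+1, k+1] = #{t : X_{t-1} = l, X_t = k}
transition_counts <- function(values, n) {
  l <- values[-length(values)]
  k <- values[-1]
  N <- matrix(0, n + 1, n + 1)
  for (t in seq_along(l)) N[l[t] + 1L, k[t] + 1L] <- N[l[t] + 1L, k[t] + 1L] + 1
  N
}

# Transition matrix and (optionally) the derivatives of log P(k|l) with
# respect to (log theta1, log theta2, nu). Row l is the convolution of the
# two CMPB component pmfs; differentiating a tilted pmf gives
#   d p_i / d log(theta) = p_i (i - mean),  d p_i / d nu = p_i (c_i - cbar)
# with c_i the log binomial coefficient, so each derivative of a row is again
# a convolution.
transition_structure <- function(n, theta1, theta2, nu, deriv = FALSE) {
  P <- matrix(0, n + 1, n + 1)
  if (deriv) d1 <- d2 <- dn <- P
  for (l in 0:n) {
    i1 <- 0:l; i2 <- 0:(n - l)
    p1 <- cmpb_pmf_vec(l, theta1, nu)
    p2 <- cmpb_pmf_vec(n - l, theta2, nu)
    row <- conv_open(p1, p2)
    P[l + 1, ] <- row
    if (deriv) {
      c1 <- lchoose(l, i1); c2 <- lchoose(n - l, i2)
      m1 <- sum(i1 * p1); m2 <- sum(i2 * p2)
      cb1 <- sum(c1 * p1); cb2 <- sum(c2 * p2)
      safe <- pmax(row, 1e-300)
      d1[l + 1, ] <- conv_open(i1 * p1, p2) / safe - m1
      d2[l + 1, ] <- conv_open(p1, i2 * p2) / safe - m2
      dn[l + 1, ] <- (conv_open(c1 * p1, p2) + conv_open(p1, c2 * p2)) / safe -
        cb1 - cb2
    }
  }
  if (deriv) list(P = P, d1 = d1, d2 = d2, dn = dn) else list(P = P)
}

#' Conditional log-likelihood of the CMPBAR(1) model
#'
#' \eqn{\ell(\eta) = \sum_{t=1}^{T} \log P_\eta(X_t \mid X_{t-1})},
#' conditioning on the first observation, so a series of length
#' \code{T + 1} contributes `T` transition terms. The likelihood depends on
#' the data only through the transition-pair counts, which makes repeated
#' evaluation during optimization cheap.
#'
#' @param series A [count_series()] (or data frame with a `value` column, or
#'   integer vector).
#' @param params A [cmpbar_params()] object.
#' @param n Range limit; taken from the series attribute when absent.
#' @return The scalar conditional log-likelihood.
#' @export
cmpbar_loglik <- function(series, params, n = NULL) {
  stopifnot(inherits(params, "cmpbar_params"))
  x <- series_values(series)
  n <- series_n(series, n %||% params$n)
  if (n != params$n) stop("series range `n` does not match params", call. = FALSE)
  if (length(x) < 2) stop("series must have length >= 2", call. = FALSE)
  if (any(x < 0 | x > n)) stop("series values outside {0, ..., n}", call. = FALSE)
  N <- transition_counts(x, n)
  P <- transition_structure(n, params$theta1, params$theta2, params$nu)$P
  sum(N * log(pmax(P, 1e-300)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# negative conditional log-likelihood and analytic gradient over
# par = (log theta1, log theta2, nu), from the pair counts
cmpbar_negll <- function(par, N, n) {
  P <- transition_structure(n, exp(par[1]), exp(par[2]), par[3])$P
  -sum(N * log(pmax(P, 1e-300)))
}

cmpbar_negll_grad <- function(par, N, n) {
  ts_ <- transition_structure(n, exp(par[1]), exp(par[2]), par[3], deriv = TRUE)
  -c(sum(N * ts_$d1), sum(N * ts_$d2), sum(N * ts_$dn))
}

# mean per-transition score in eta = (theta1, theta2, nu) coordinates
cmpbar_mean_score <- function(eta, N, n) {
  ts_ <- transition_structure(n, eta[1], eta[2], eta[3], deriv = TRUE)
  c(sum(N * ts_$d1) / eta[1], sum(N * ts_$d2) / eta[2], sum(N * ts_$dn)) /
    sum(N)
}

#' Asymptotic covariance of the CML estimator
#'
#' Estimates the sandwich covariance \eqn{J^{-1} I J^{-1} / T} of Theorem-2
#' type asymptotics for conditional maximum likelihood on an ergodic finite
#' chain: \eqn{\hat I} is the average outer product of per-transition score
#' vectors (computed analytically) and \eqn{\hat J} the average per-transition
#' Hessian of the log transition probability (central finite differences of
#' the analytic gradient, then symmetrized). The Hessian-only alternative
#' \eqn{(-\hat J)^{-1} / T} — the usual observed-information covariance,
#' exact when the model is correctly specified — is available as
#' `type = "hessian"`.
#'
#' @param series A [count_series()].
#' @param params A [cmpbar_params()] at (or near) the CML optimum.
#' @param type `"sandwich"` or `"hessian"`.
#' @param n Range limit override.
#' @return A symmetric 3x3 covariance matrix for \code{(theta1, theta2, nu)}.
#' @export
cmpbar_covariance <- function(series, params, type = c("sandwich", "hessian"),
                              n = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(params, "cmpbar_params"))
  x <- series_values(series)
  n <- series_n(series, n %||% params$n)
  N <- transition_counts(x, n)
  T_ <- sum(N)
  eta <- c(params$theta1, params$theta2, params$nu)

  # I-hat: average outer product of analytic per-transition scores
  ts_ <- transition_structure(n, eta[1], eta[2], eta[3], deriv = TRUE)
  I_hat <- matrix(0, 3, 3)
  nz <- which(N > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    l <- nz[r, 1]; k <- nz[r, 2]
    s <- c(ts_$d1[l, k] / eta[1], ts_$d2[l, k] / eta[2], ts_$dn[l, k])
    I_hat <- I_hat + N[l, k] * tcrossprod(s)
  }
  I_hat <- I_hat / T_

  # J-hat: central differences of the mean score
  J_hat <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-5 * max(abs(eta[j]), 1e-3)
    ep <- em <- eta; ep[j] <- eta[j] + h; em[j] <- eta[j] - h
    J_hat[, j] <- (cmpbar_mean_score(ep, N, n) -
                     cmpbar_mean_score(em, N, n)) / (2 * h)
  }
  J_hat <- (J_hat + t(J_hat)) / 2

  kappa <- kappa(-J_hat, exact = TRUE)
  if (!is.finite(kappa) || kappa > 1e10) {
    warning(sprintf(
      "near-singular information matrix (condition number %.3g): a flat direction, likely nu", kappa))
  }
  Jinv <- solve(J_hat)
  V <- switch(type,
              sandwich = Jinv %*% I_hat %*% Jinv / T_,
              hessian = solve(-J_hat) / T_)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(c("theta1", "theta2", "nu"), c("theta1", "theta2", "nu"))
  V
}

new_fit_result <- function(model, estimates, se, covariance, loglik, k, T_,
                           converged, iterations, init, n, grad_norm = NA_real_) {
  ic <- information_criteria(loglik, k, T_)
  structure(list(model = model, n = n, estimates = estimates, se = se,
                 covariance = covariance, loglik = loglik, aic = ic$aic,
                 bic = ic$bic, n_transitions = T_, converged = converged,
                 iterations = iterations, init = init, grad_norm = grad_norm),
            class = "cmpbar_fit")
}

# moment-based starting point: pi from the sample mean, rho from lag-1
# autocorrelation, nu at the neutral binomial submodel
cmpbar_moment_init <- function(x, n) {
  pi0 <- min(max(mean(x) / n, 0.02), 0.98)
  rho0 <- if (length(x) > 2 && stats::sd(x) > 0) {
    stats::cor(x[-1], x[-length(x)])
  } else 0
  rho_min <- max(-pi0 / (1 - pi0), -(1 - pi0) / pi0)
  rho0 <- min(max(rho0, rho_min + 0.05), 0.9)
  beta0 <- (1 - rho0) * pi0
  alpha0 <- beta0 + rho0
  c(log(alpha0 / (1 - alpha0)), log(beta0 / (1 - beta0)), 1)
}

#' Conditional maximum likelihood fit of the CMPBAR(1) model
#'
#' Maximizes the conditional log-likelihood over the unconstrained
#' coordinates \code{(log theta1, log theta2, nu)} by BFGS with the analytic
#' gradient. The default start sets `nu = 1` (the binomial AR(1) submodel)
#' with `theta1`, `theta2` from a moment fit of that submodel (sample mean
#' and lag-1 autocorrelation). If the first search does not converge, a small
#' multi-start fallback over perturbed `nu` values is tried and the best
#' optimum kept; a still-unconverged result is flagged, never silent.
#'
#' @param series A [count_series()] (or data frame with `value`, or vector).
#' @param n Range limit; taken from the series attribute when absent.
#' @param init Optional starting vector `c(theta1, theta2, nu)`.
#' @param se `"hessian"` (default, observed-information) or `"sandwich"`
#'   (robust), or `"none"` to skip covariance work.
#' @return A `"cmpbar_fit"` object: estimates `(theta1, theta2, nu)`,
#'   standard errors, covariance, log-likelihood, AIC/BIC with
#'   \code{k = 3} free parameters and `T` = number of transitions,
#'   convergence metadata. Methods: [tidy()], [glance()], `print()`.
#' @examples
#' p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 0.25, nu = 1)
#' y <- cmpbar_simulate(p, T = 300, seed = 1)
#' fit <- cmpbar_fit(y)
#' tidy(fit)
#' glance(fit)
#' @export
cmpbar_fit <- function(series, n = NULL, init = NULL,
                       se = c("hessian", "sandwich", "none")) {
  se <- match.arg(se)
  x <- series_values(series)
  n <- series_n(series, n)
  if (length(x) < 2) stop("series must have length >= 2", call. = FALSE)
  if (any(x < 0 | x > n)) stop("series values outside {0, ..., n}", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate series (constant): parameters are not identifiable",
         call. = FALSE)
  }
  N <- transition_counts(x, n)
  par0 <- if (is.null(init)) {
    cmpbar_moment_init(x, n)
  } else {
    stopifnot(length(init) == 3, init[1] > 0, init[2] > 0)
    c(log(init[1]), log(init[2]), init[3])
  }
  run <- function(p0) {
    stats::optim(p0, cmpbar_negll, cmpbar_negll_grad, N = N, n = n,
                 method = "BFGS", control = list(maxit = 300))
  }
  opt <- run(par0)
  if (opt$convergence != 0) {
    alts <- lapply(list(par0 + c(0.3, -0.3, -0.7), par0 + c(-0.3, 0.3, 0.7)), run)
    alts <- c(list(opt), alts)
    vals <- vapply(alts, function(o) o$value, 0)
    opt <- alts[[which.min(vals)]]
  }
  est <- c(theta1 = exp(opt$par[1]), theta2 = exp(opt$par[2]), nu = opt$par[3])
  grad_norm <- sqrt(sum(cmpbar_negll_grad(opt$par, N, n)^2))
  params_hat <- cmpbar_params(n = n, theta1 = est[1], theta2 = est[2],
                              nu = est[3])
  V <- matrix(NA_real_, 3, 3)
  se_vec <- rep(NA_real_, 3)
  if (se != "none") {
    V <- cmpbar_covariance(x, params_hat, type = se, n = n)
    se_vec <- sqrt(pmax(diag(V), 0))
  }
  names(se_vec) <- names(est)
  new_fit_result("cmpbar", est, se_vec, V, loglik = -opt$value, k = 3,
                 T_ = sum(N), converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]],
                 init = c(theta1 = exp(par0[1]), theta2 = exp(par0[2]),
                          nu = par0[3]),
                 n = n, grad_norm = grad_norm)
}

# BAR(1) transition matrix: Binomial(l, alpha) * Binomial(n-l, beta)
bar1_transition_matrix <- function(n, alpha, beta) {
  P <- matrix(0, n + 1, n + 1)
  for (l in 0:n) {
    P[l + 1, ] <- conv_open(stats::dbinom(0:l, l, alpha),
                            stats::dbinom(0:(n - l), n - l, beta))
  }
  P
}

bar1_negll_pirho <- function(pi_, rho, N, n) {
  beta <- (1 - rho) * pi_
  alpha <- beta + rho
  P <- bar1_transition_matrix(n, alpha, beta)
  -sum(N * log(pmax(P, 1e-300)))
}

#' Conditional maximum likelihood fit of the binomial AR(1) competitor
#'
#' Fits the classical binomial AR(1) model — independent Bernoulli counting
#' series, transition law the convolution of \code{Binomial(l, alpha)} and
#' \code{Binomial(n - l, beta)} — in the \code{(pi, rho)} parameterization
#' with \code{alpha = beta + rho}, \code{beta = (1 - rho) pi},
#' \code{pi in (0,1)} and \code{rho in (max(-pi/(1-pi), -(1-pi)/pi), 1)}.
#' The constraint region is handled by a logistic reparameterization;
#' standard errors come from the observed information in \code{(pi, rho)}.
#' This model is the `nu = 1` submodel of the CMPBAR(1), with two free
#' parameters.
#'
#' @inheritParams cmpbar_fit
#' @return A `"cmpbar_fit"` object with `model = "bar1"` and estimates
#'   `(pi, rho)`.
#' @export
bar1_fit <- function(series, n = NULL, init = NULL) {
  x <- series_values(series)
  n <- series_n(series, n)
  if (length(x) < 2) stop("series must have length >= 2", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate series (constant): parameters are not identifiable",
         call. = FALSE)
  }
  N <- transition_counts(x, n)
  to_pirho <- function(u) {
    pi_ <- stats::plogis(u[1])
    rho_min <- max(-pi_ / (1 - pi_), -(1 - pi_) / pi_)
    rho <- rho_min + (1 - rho_min) * stats::plogis(u[2])
    c(pi_, rho)
  }
  fn <- function(u) {
    pr <- to_pirho(u)
    bar1_negll_pirho(pr[1], pr[2], N, n)
  }
  u0 <- if (is.null(init)) {
    p0 <- cmpbar_moment_init(x, n)
    a0 <- stats::plogis(p0[1]); b0 <- stats::plogis(p0[2])
    rho0 <- a0 - b0; pi0 <- b0 / (1 - rho0)
    pi0 <- min(max(pi0, 0.02), 0.98)
    rho_min <- max(-pi0 / (1 - pi0), -(1 - pi0) / pi0)
    frac <- min(max((rho0 - rho_min) / (1 - rho_min), 0.05), 0.95)
    c(stats::qlogis(pi0), stats::qlogis(frac))
  } else {
    pi0 <- init[1]; rho0 <- init[2]
    rho_min <- max(-pi0 / (1 - pi0), -(1 - pi0) / pi0)
    c(stats::qlogis(pi0), stats::qlogis((rho0 - rho_min) / (1 - rho_min)))
  }
  opt <- stats::optim(u0, fn, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
  est <- to_pirho(opt$par)
  names(est) <- c("pi", "rho")
  H <- numDeriv::hessian(function(pr) -bar1_negll_pirho(pr[1], pr[2], N, n),
                         est)
  V <- solve(-(H + t(H)) / 2)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(est), names(est))
  se_vec <- sqrt(pmax(diag(V), 0))
  new_fit_result("bar1", est, se_vec, V, loglik = -opt$value, k = 2,
                 T_ = sum(N), converged = opt$convergence == 0,
                 iterations = opt$counts[["function"]],
                 init = to_pirho(u0), n = n)
}

#' Information criteria
#'
#' \code{AIC = 2k - 2 loglik}; \code{BIC = k log(T) - 2 loglik}, with `T` the
#' number of transitions the conditional likelihood actually uses (series
#' length minus one).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param T Effective sample size.
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(loglik, k, T) {
  stopifnot(k >= 0, T >= 1)
  tibble::tibble(aic = 2 * k - 2 * loglik, bic = k * log(T) - 2 * loglik)
}

#' @export
print.cmpbar_fit <- function(x, ...) {
  cat(sprintf("%s fit by conditional maximum likelihood (n = %d, T = %d)\n",
              toupper(x$model), x$n, x$n_transitions))
  tab <- rbind(estimate = x$estimates, `std. error` = x$se)
  print(round(tab, 4))
  cat(sprintf("logLik %.4f   AIC %.4f   BIC %.4f   converged: %s\n",
              x$loglik, x$aic, x$bic, x$converged))
  invisible(x)
}

#' Tidy a CMPBAR/BAR fit
#'
#' @param x A `"cmpbar_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy cmpbar_fit
#' @export
tidy.cmpbar_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates),
                 estimate = unname(x$estimates),
                 std.error = unname(x$se))
}

#' One-row summary of a CMPBAR/BAR fit
#'
#' @param x A `"cmpbar_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `logLik`, `AIC`, `BIC`, `nobs`
#'   (transitions), `converged`, `iterations`.
#' @method glance cmpbar_fit
#' @export
glance.cmpbar_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$aic, BIC = x$bic,
                 nobs = x$n_transitions, converged = x$converged,
                 iterations = x$iterations)
}

#' Extract the fitted process parameters from a fit
#'
#' Returns the [cmpbar_params()] implied by a fitted model, mapping a BAR(1)
#' fit's \code{(pi, rho)} back to \code{(alpha, beta)} with `nu = 1`. Useful
#' for feeding a fit into the diagnostics functions.
#'
#' @param fit A `"cmpbar_fit"` object.
#' @return A [cmpbar_params()] object.
#' @export
fit_params <- function(fit) {
  stopifnot(inherits(fit, "cmpbar_fit"))
  if (fit$model == "cmpbar") {
    cmpbar_params(n = fit$n, theta1 = fit$estimates[["theta1"]],
                  theta2 = fit$estimates[["theta2"]],
                  nu = fit$estimates[["nu"]])
  } else {
    pi_ <- fit$estimates[["pi"]]; rho <- fit$estimates[["rho"]]
    beta <- (1 - rho) * pi_; alpha <- beta + rho
    cmpbar_params(n = fit$n, alpha = alpha, beta = beta, nu = 1)
  }
}
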