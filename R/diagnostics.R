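#' Pearson residuals of a fitted CMPBAR(1) model
#'
#' \eqn{r_t = (X_t - E[X_t|X_{t-1}]) / \sqrt{Var(X_t|X_{t-1})}} for
#' \eqn{t = 1..T}, using the exact conditional moments of the model. Under a
#' correctly specified model the residuals are approximately white with mean
#' 0 and variance 1.
#'
#' @param series A [count_series()].
#' @param params A [cmpbar_params()] (typically [fit_params()] of a fit).
#' @param n Range limit override.
#' @return A tibble with columns `t`, `observed`, `mean`, `sd`, `residual`
#'   (`t` indexes transitions, 1..T).
#' @export
pearson_residuals <- function(series, params, n = NULL) {
  stopifnot(inherits(params, "cmpbar_params"))
  x <- series_values(series)
  n <- series_n(series, n %||% params$n)
  if (n != params$n) stop("series range `n` does not match params", call. = FALSE)
  cm <- cmpbar_conditional_moments(params, from = 0:n)
  l <- x[-length(x)]
  k <- x[-1]
  mu <- cm$mean[l + 1L]
  sd_ <- sqrt(cm$variance[l + 1L])
  tibble::tibble(t = seq_along(k), observed = k, mean = mu, sd = sd_,
                 residual = (k - mu) / sd_)
}

#' Non-randomized PIT histogram for a fitted CMPBAR(1) model
#'
#' The probability integral transform adapted to discrete data: for each
#' transition the conditional cdf values \code{F(x_t - 1 | x_{t-1})} and
#' \code{F(x_t | x_{t-1})} bracket a linearly interpolated cdf segment on
#' \[0, 1\]; averaging those segments over `t` (the mean-PIT construction)
#' yields a deterministic histogram. Under an adequate model it is close to
#' uniform.
#'
#' @param series A [count_series()].
#' @param params A [cmpbar_params()].
#' @param bins Number of equal-width bins on \[0, 1\] (default 10).
#' @param n Range limit override.
#' @return A tibble of class `"cmpbar_pit"` with columns `bin`, `lower`,
#'   `upper`, `mass` (masses sum to 1).
#' @export
pit_histogram <- function(series, params, bins = 10, n = NULL) {
  stopifnot(inherits(params, "cmpbar_params"), bins >= 2)
  x <- series_values(series)
  n <- series_n(series, n %||% params$n)
  if (n != params$n) stop("series range `n` does not match params", call. = FALSE)
  P <- cmpbar_transition_matrix(params)
  cdf <- t(apply(P, 1, cumsum))
  l <- x[-length(x)]
  k <- x[-1]
  hi <- cdf[cbind(l + 1L, k + 1L)]
  lo <- ifelse(k == 0, 0, cdf[cbind(l + 1L, pmax(k, 1L))])
  # mean PIT evaluated at the bin edges
  Fbar <- function(u) {
    mean(pmin(pmax((u - lo) / (hi - lo), 0), 1))
  }
  edges <- seq(0, 1, length.out = bins + 1)
  Fvals <- vapply(edges, Fbar, 0)
  out <- tibble::tibble(bin = seq_len(bins),
                        lower = edges[-(bins + 1)],
                        upper = edges[-1],
                        mass = diff(Fvals))
  class(out) <- c("cmpbar_pit", class(out))
  out
}

#' Sample autocorrelation and partial autocorrelation of a series
#'
#' Thin tidy wrapper over [stats::acf()] / [stats::pacf()] for display of the
#' serial-dependence structure (an AR(1)-like geometric ACF decay and a
#' single significant PACF spike are the signature of these models).
#'
#' @param series A [count_series()] or numeric vector.
#' @param lag_max Maximum lag.
#' @return A tibble with columns `lag`, `acf`, `pacf` (`pacf` is `NA` at lag
#'   0, where it is undefined; `acf` at lag 0 is 1).
#' @export
series_acf <- function(series, lag_max = 20) {
  x <- as.numeric(series_values(series))
  stopifnot(lag_max < length(x))
  a <- stats::acf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  p <- stats::pacf(x, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  tibble::tibble(lag = 0:lag_max, acf = a, pacf = c(NA_real_, p))
}

#' Full diagnostic report for a fitted model
#'
#' Bundles Pearson residual summaries, a Ljung-Box whiteness test on the
#' residuals, and the PIT histogram with a chi-square uniformity test.
#'
#' @param series A [count_series()].
#' @param fit A `"cmpbar_fit"` object (or a [cmpbar_params()]).
#' @param pit_bins Bins for the PIT histogram.
#' @param lb_lag Ljung-Box lag.
#' @return A list of class `"cmpbar_diagnostics"`: `residuals` (tibble),
#'   `residual_mean`, `residual_variance`, `ljung_box` (htest), `pit`
#'   (tibble), `pit_chisq_p`.
#' @export
cmpbar_diagnostics <- function(series, fit, pit_bins = 10, lb_lag = 10) {
  params <- if (inherits(fit, "cmpbar_fit")) fit_params(fit) else fit
  res <- pearson_residuals(series, params)
  pit <- pit_histogram(series, params, bins = pit_bins)
  T_ <- nrow(res)
  expected <- T_ / pit_bins
  stat <- sum((pit$mass * T_ - expected)^2 / expected)
  pit_p <- stats::pchisq(stat, df = pit_bins - 1, lower.tail = FALSE)
  structure(list(residuals = res,
                 residual_mean = mean(res$residual),
                 residual_variance = stats::var(res$residual),
                 ljung_box = stats::Box.test(res$residual, lag = lb_lag,
                                             type = "Ljung-Box"),
                 pit = pit, pit_chisq_p = pit_p),
            class = "cmpbar_diagnostics")
}

#' @export
print.cmpbar_diagnostics <- function(x, ...) {
  cat(sprintf("Pearson residuals: mean %.4f, variance %.4f\n",
              x$residual_mean, x$residual_variance))
  cat(sprintf("Ljung-Box (lag %d): p = %.4f\n",
              x$ljung_box$parameter, x$ljung_box$p.value))
  cat(sprintf("PIT uniformity (chi-square, %d bins): p = %.4f\n",
              nrow(x$pit), x$pit_chisq_p))
  invisible(x)
}

#' Plot a PIT histogram
#'
#' @param object A `"cmpbar_pit"` tibble from [pit_histogram()].
#' @param ... Unused.
#' @return A ggplot: bin masses with the uniform reference line.
#' @method autoplot cmpbar_pit
#' @export
autoplot.cmpbar_pit <- function(object, ...) {
  bins <- nrow(object)
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$lower + .data$upper) / 2,
                                       y = .data$mass)) +
    ggplot2::geom_col(width = 1 / bins, fill = "grey35", colour = "white") +
    ggplot2::geom_hline(yintercept = 1 / bins, linetype = 2) +
    ggplot2::labs(x = "PIT", y = "relative frequency") +
    ggplot2::theme_minimal()
}

#' Residual diagnostic plots for a fitted model
#'
#' Residual trace with a zero line; useful alongside [series_acf()] and
#' [autoplot.cmpbar_pit()].
#'
#' @param series A [count_series()].
#' @param fit A `"cmpbar_fit"` or [cmpbar_params()].
#' @return A ggplot of the Pearson residual series.
#' @export
plot_residuals <- function(series, fit) {
  params <- if (inherits(fit, "cmpbar_fit")) fit_params(fit) else fit
  res <- pearson_residuals(series, params)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$t, y = .data$residual)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "t", y = "Pearson residual") +
    ggplot2::theme_minimal()
}
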