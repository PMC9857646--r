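test_that("conditional log-likelihood reduces to a single transition for a pair", {
  p <- cmpbar_params(n = 7, theta1 = 0.8, theta2 = 1.1, nu = 0.4)
  y <- count_series(c(3, 5), n = 7)
  expect_equal(cmpbar_loglik(y, p), cmpbar_transition(p, 3, 5, log = TRUE))
})

test_that("log-likelihood is a pure function of consecutive pairs", {
  p <- cmpbar_params(n = 7, theta1 = 0.8, theta2 = 1.1, nu = 0.4)
  x <- c(3, 5, 2, 2, 7, 0, 4)
  ll <- cmpbar_loglik(count_series(x, 7), p)
  by_pairs <- sum(vapply(seq_len(length(x) - 1), function(t)
    cmpbar_transition(p, x[t], x[t + 1], log = TRUE), 0))
  expect_equal(ll, by_pairs, tolerance = 1e-12)
})

test_that("nu = 1 log-likelihood matches the binomial convolution oracle", {
  p <- cmpbar_params(n = 10, alpha = 0.45, beta = 0.3, nu = 1)
  set.seed(13)
  x <- sample(0:10, 60, replace = TRUE)
  ll <- cmpbar_loglik(count_series(x, 10), p)
  oracle <- sum(vapply(seq_len(59), function(t)
    log(oracle_binconv_row(10, x[t], 0.45, 0.3, x[t + 1])), 0))
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("BAR(1) and CMPBAR likelihoods coincide on the nu = 1 submodel", {
  pi_ <- 0.55; rho <- 0.13
  beta <- (1 - rho) * pi_; alpha <- beta + rho
  p <- cmpbar_params(n = 7, alpha = alpha, beta = beta, nu = 1)
  y <- cmpbar_simulate(p, T = 300, seed = 17)
  N <- cmpbar:::transition_counts(y$value, 7)
  ll_bar <- -cmpbar:::bar1_negll_pirho(pi_, rho, N, 7)
  expect_equal(ll_bar, cmpbar_loglik(y, p), tolerance = 1e-8)
})

test_that("CML recovers parameters within sampling error at T = 500", {
  truth <- c(0.25, 0.25, 1)
  p <- cmpbar_params(n = 10, theta1 = truth[1], theta2 = truth[2], nu = truth[3])
  y <- cmpbar_simulate(p, T = 500, seed = 2024)
  fit <- cmpbar_fit(y)
  # one draw from the sampling distribution: compare against 3x its known
  # finite-sample spread (theta1, theta2, nu) at this design point
  spread <- c(0.0586, 0.0313, 0.0997)
  expect_true(all(abs(fit$estimates - truth) < 3 * spread))
  expect_true(fit$converged)
})

test_that("the fit is a stationary point and a local maximum", {
  p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 1, nu = 0.5)
  y <- cmpbar_simulate(p, T = 400, seed = 31)
  fit <- cmpbar_fit(y)
  expect_lt(fit$grad_norm, 1e-2)
  ll_hat <- fit$loglik
  est <- fit$estimates
  for (j in 1:3) {
    for (s in c(-0.05, 0.05)) {
      pert <- est; pert[j] <- pert[j] + s
      p_pert <- cmpbar_params(n = 10, theta1 = pert[1], theta2 = pert[2],
                              nu = pert[3])
      expect_lt(cmpbar_loglik(y, p_pert), ll_hat)
    }
  }
})

test_that("the optimum is invariant to the starting point", {
  p <- cmpbar_params(n = 10, theta1 = 1, theta2 = 1.5, nu = 1.5)
  y <- cmpbar_simulate(p, T = 300, seed = 41)
  fits <- lapply(list(NULL, c(0.5, 0.5, 0.5), c(2, 2, 2)), function(init)
    cmpbar_fit(y, init = init, se = "none"))
  lls <- vapply(fits, function(f) f$loglik, 0)
  expect_lt(max(lls) - min(lls), 1e-4)
})

test_that("analytic scores match numerical differentiation", {
  p <- cmpbar_params(n = 10, theta1 = 0.4, theta2 = 0.9, nu = 0.7)
  y <- cmpbar_simulate(p, T = 200, seed = 51)
  N <- cmpbar:::transition_counts(y$value, 10)
  par <- c(log(0.5), log(1.1), 0.5)
  g_num <- numDeriv::grad(cmpbar:::cmpbar_negll, par, N = N, n = 10)
  expect_equal(cmpbar:::cmpbar_negll_grad(par, N, 10), g_num,
               tolerance = 1e-6)
})

test_that("covariance estimators are symmetric, PSD, and shrink like 1/sqrt(T)", {
  p <- cmpbar_params(n = 10, alpha = 0.4, beta = 0.3, nu = 1)
  fits <- lapply(c(1000, 4000), function(T_) {
    y <- cmpbar_simulate(p, T = T_, seed = 6000 + T_)
    cmpbar_fit(y, se = "sandwich")
  })
  for (f in fits) {
    V <- f$covariance
    expect_lt(max(abs(V - t(V))), 1e-8)
    expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
  }
  ratio <- fits[[2]]$se / fits[[1]]$se
  expect_true(all(abs(ratio - 0.5) < 0.25 * 0.5 + 0.1))
})

test_that("information-matrix equality holds approximately under correct specification", {
  p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 1, nu = 1)
  y <- cmpbar_simulate(p, T = 4000, seed = 71)
  fit <- cmpbar_fit(y, se = "none")
  params_hat <- cmpbar_params(n = 10, theta1 = fit$estimates[1],
                              theta2 = fit$estimates[2], nu = fit$estimates[3])
  V_sand <- cmpbar_covariance(y, params_hat, type = "sandwich")
  V_hess <- cmpbar_covariance(y, params_hat, type = "hessian")
  # trace(J^-1 I) = k when I = -J; equivalently V_sand ~ V_hess
  tr <- sum(diag(solve(V_hess, V_sand)))
  expect_lt(abs(tr - 3), 0.8)
})

test_that("BAR(1) CML recovers (pi, rho) and reports k = 2 criteria", {
  pi_ <- 0.55; rho <- 0.13
  beta <- (1 - rho) * pi_; alpha <- beta + rho
  p <- cmpbar_params(n = 7, alpha = alpha, beta = beta, nu = 1)
  y <- cmpbar_simulate(p, T = 5000, seed = 81)
  fit <- bar1_fit(y)
  expect_lt(abs(fit$estimates[["pi"]] - pi_), 3 * fit$se[["pi"]])
  expect_lt(abs(fit$estimates[["rho"]] - rho), 3 * fit$se[["rho"]])
  expect_equal(fit$aic, 4 - 2 * fit$loglik)
  # and the CMPBAR likelihood at the mapped estimates with nu = 1 agrees
  est <- fit$estimates
  b_hat <- (1 - est[["rho"]]) * est[["pi"]]
  p_hat <- cmpbar_params(n = 7, alpha = b_hat + est[["rho"]], beta = b_hat,
                         nu = 1)
  expect_equal(fit$loglik, cmpbar_loglik(y, p_hat), tolerance = 1e-6)
})

test_that("information criteria follow the standard formulas", {
  ic <- information_criteria(-622.6669, k = 3, T = 313)
  expect_equal(ic$aic, 1251.3338)
  expect_lt(abs(ic$aic - 1251.3337), 2e-4)  # printed to 4 dp
  expect_lt(abs(ic$bic - 1262.5723), 2e-4)
  expect_equal(information_criteria(0, 0, 1), tibble::tibble(aic = 0, bic = 0))
  ic2 <- information_criteria(-100, 3, 50)
  expect_equal(ic2$bic - ic2$aic, 3 * (log(50) - 2))
})

test_that("degenerate and invalid series are rejected loudly", {
  expect_error(cmpbar_fit(count_series(rep(0, 30), 5)), "identifiable")
  expect_error(cmpbar_fit(count_series(rep(5, 30), 5)), "identifiable")
  expect_error(bar1_fit(count_series(rep(2, 30), 5)), "identifiable")
  expect_error(cmpbar_fit(c(1, 2, 3)), "n")
})

test_that("tidy and glance expose the fit in broom shape", {
  p <- cmpbar_params(n = 7, theta1 = 1, theta2 = 1, nu = 1)
  y <- cmpbar_simulate(p, T = 150, seed = 91)
  fit <- cmpbar_fit(y)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$term, c("theta1", "theta2", "nu"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 149)
  expect_equal(gl$model, "cmpbar")
  expect_true(all(is.finite(td$std.error)))
})
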