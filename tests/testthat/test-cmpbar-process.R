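params_grid <- list(
  cmpbar_params(n = 10, theta1 = 0.25, theta2 = 0.25, nu = 0.5),
  cmpbar_params(n = 10, theta1 = 0.25, theta2 = 1.5, nu = 1),
  cmpbar_params(n = 7, theta1 = 1.2, theta2 = 0.95, nu = -0.5),
  cmpbar_params(n = 5, theta1 = 1, theta2 = 1.5, nu = 2))

test_that("transition matrices are row-stochastic with strictly positive entries", {
  for (p in params_grid) {
    P <- cmpbar_transition_matrix(p)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_gt(min(P), 0)
  }
})

test_that("direct Eq-style transition sum agrees with the convolution assembly", {
  for (p in params_grid) {
    P <- cmpbar_transition_matrix(p)
    for (l in c(0, 2, p$n)) {
      direct <- vapply(0:p$n, function(k) cmpbar_transition(p, l, k), 0)
      expect_equal(direct, unname(P[l + 1, ]), tolerance = 1e-12)
    }
  }
})

test_that("from state 0 only the revival thinning contributes", {
  p <- cmpbar_params(n = 8, theta1 = 0.7, theta2 = 1.3, nu = 0.6)
  row0 <- vapply(0:8, function(k) cmpbar_transition(p, 0, k), 0)
  expect_equal(row0, dcmpb(0:8, cmpb(8, theta = 1.3, nu = 0.6)),
               tolerance = 1e-12)
})

test_that("nu = 1 transition rows are the binomial convolution", {
  p <- cmpbar_params(n = 10, alpha = 0.4, beta = 0.25, nu = 1)
  P <- cmpbar_transition_matrix(p)
  for (l in 0:10) {
    oracle <- vapply(0:10, function(k)
      oracle_binconv_row(10, l, 0.4, 0.25, k), 0)
    expect_equal(unname(P[l + 1, ]), oracle, tolerance = 1e-12)
  }
})

test_that("n = 1 transition matrix matches the two-state hand computation", {
  p <- cmpbar_params(n = 1, theta1 = 0.5, theta2 = 2, nu = 0.8)
  P <- cmpbar_transition_matrix(p)
  # one unit: survival is Bernoulli(alpha), revival Bernoulli(beta); nu is
  # irrelevant at n = 1 because both binomial coefficients are 1
  hand <- rbind(c(1 - p$beta, p$beta), c(1 - p$alpha, p$alpha))
  expect_equal(unname(P), hand, tolerance = 1e-12)
})

test_that("stationary distribution solves pi P = pi and reduces to the binomial at nu = 1", {
  for (p in params_grid) {
    pi_ <- cmpbar_stationary(p)$prob
    P <- cmpbar_transition_matrix(p)
    expect_lt(max(abs(pi_ %*% P - pi_)), 1e-12)
    expect_lt(abs(sum(pi_) - 1), 1e-12)
    expect_gt(min(pi_), 0)
  }
  # nu = 1, alpha = beta: marginal Binomial(n, alpha)
  p <- cmpbar_params(n = 6, alpha = 0.35, beta = 0.35, nu = 1)
  expect_equal(cmpbar_stationary(p)$prob, dbinom(0:6, 6, 0.35),
               tolerance = 1e-10)
  # nu = 1 general: Binomial(n, beta / (1 - rho)), rho = alpha - beta
  p <- cmpbar_params(n = 10, alpha = 0.5, beta = 0.3, nu = 1)
  expect_equal(cmpbar_stationary(p)$prob, dbinom(0:10, 10, 0.3 / (1 - 0.2)),
               tolerance = 1e-10)
})

test_that("conditional moments match the transition-row moments and closed forms", {
  for (p in params_grid) {
    P <- cmpbar_transition_matrix(p)
    cm <- cmpbar_conditional_moments(p)
    for (l in 0:p$n) {
      k <- 0:p$n
      mu_row <- sum(k * P[l + 1, ])
      var_row <- sum(k^2 * P[l + 1, ]) - mu_row^2
      expect_lt(abs(cm$mean[l + 1] - mu_row), 1e-10)
      expect_lt(abs(cm$variance[l + 1] - var_row), 1e-10)
    }
  }
  # nu = 1: conditional variance l a(1-a) + (n-l) b(1-b)
  p <- cmpbar_params(n = 9, alpha = 0.4, beta = 0.2, nu = 1)
  cm <- cmpbar_conditional_moments(p)
  l <- 0:9
  expect_equal(cm$variance, l * 0.4 * 0.6 + (9 - l) * 0.2 * 0.8,
               tolerance = 1e-10)
  # from state 0: moments of the revival component alone
  p <- params_grid[[1]]
  m0 <- cmpb_moments(cmpb(p$n, theta = p$theta2, nu = p$nu))
  cm <- cmpbar_conditional_moments(p, from = 0)
  expect_equal(cm$mean, m0$mean, tolerance = 1e-12)
  expect_equal(cm$variance, m0$variance, tolerance = 1e-12)
})

test_that("CBID is consistent with the conditional moments", {
  p <- params_grid[[3]]
  cm <- cmpbar_conditional_moments(p)
  expect_equal(cmpbar_cbid(p),
               p$n * cm$variance / (cm$mean * (p$n - cm$mean)),
               tolerance = 1e-12)
  # nu = 1 with alpha = beta: the conditional law is Binomial(n, alpha), so
  # CBID is exactly 1 in every state (alpha != beta convolutions are
  # under-dispersed relative to a single binomial, so CBID < 1 there)
  p1 <- cmpbar_params(n = 10, alpha = 0.4, beta = 0.4, nu = 1)
  expect_lt(max(abs(cmpbar_cbid(p1) - 1)), 1e-10)
  p2 <- cmpbar_params(n = 10, alpha = 0.6, beta = 0.2, nu = 1)
  expect_true(all(cmpbar_cbid(p2) <= 1 + 1e-12))
})

test_that("stationary BID sits in the regime dictated by nu", {
  th <- list(c(0.25, 0.25), c(0.25, 1), c(0.25, 1.5), c(1, 1.5))
  for (t2 in th) {
    expect_gt(cmpbar_stationary_bid(
      cmpbar_params(n = 10, theta1 = t2[1], theta2 = t2[2], nu = 0.5)), 1)
    expect_lt(abs(cmpbar_stationary_bid(
      cmpbar_params(n = 10, theta1 = t2[1], theta2 = t2[2], nu = 1)) - 1), 1e-8)
    expect_lt(cmpbar_stationary_bid(
      cmpbar_params(n = 10, theta1 = t2[1], theta2 = t2[2], nu = 1.5)), 1)
  }
})

test_that("simulated paths stay in range and track the exact stationary law", {
  p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 0.25, nu = 0.5)
  y <- cmpbar_simulate(p, T = 100000, seed = 5)
  expect_true(all(y$value >= 0 & y$value <= 10))
  expect_gt(gof_pvalue(y$value, cmpbar_stationary(p)$prob), 0.01)
  # one-step transition frequencies from the modal state match the row
  P <- cmpbar_transition_matrix(p)
  l_star <- which.max(tabulate(y$value + 1L, 11)) - 1L
  nxt <- y$value[-1][y$value[-nrow(y)] == l_star]
  expect_gt(gof_pvalue(nxt, P[l_star + 1, ]), 0.01)
})

test_that("sample BID of a path agrees with the exact stationary BID", {
  p <- cmpbar_params(n = 10, theta1 = 0.25, theta2 = 1, nu = 0.5)
  y <- cmpbar_simulate(p, T = 5000, seed = 9)
  expect_lt(abs(sample_bid(y) - cmpbar_stationary_bid(p)), 0.15)
})

test_that("explicit starts, burn-in, and bad inputs behave", {
  p <- cmpbar_params(n = 5, theta1 = 0.5, theta2 = 0.5, nu = 1)
  y <- cmpbar_simulate(p, T = 10, init = 3, burnin = 0, seed = 2)
  expect_equal(nrow(y), 10)
  expect_error(cmpbar_simulate(p, T = 10, init = 9), "init")
  expect_identical(cmpbar_simulate(p, T = 20, seed = 3)$value,
                   cmpbar_simulate(p, T = 20, seed = 3)$value)
})
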