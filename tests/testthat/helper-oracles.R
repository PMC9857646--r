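# Independent brute-force oracles, kept deliberately naive: direct summation
# in the probability domain, full enumeration of binary vectors, and binomial
# convolution. They never call the package's log-domain code paths.

# normalizer S(theta, nu) by direct term-by-term summation
oracle_normalizer <- function(n, theta, nu) {
  sum(choose(n, 0:n)^nu * theta^(0:n))
}

# CMPB pmf at x by marginalizing the exchangeable joint pmf over {0,1}^n
oracle_pmf_via_joint <- function(n, theta, nu, x) {
  z <- as.matrix(expand.grid(rep(list(0:1), n)))
  sums <- rowSums(z)
  w <- choose(n, sums)^(nu - 1) * theta^sums
  sum(w[sums == x]) / sum(w)
}

# CMPB pmf vector by direct summation
oracle_pmf_vec <- function(n, theta, nu) {
  terms <- choose(n, 0:n)^nu * theta^(0:n)
  terms / sum(terms)
}

# Binomial(l, alpha) * Binomial(n - l, beta) convolution row (the nu = 1
# transition law), by direct summation
oracle_binconv_row <- function(n, l, alpha, beta, k) {
  i <- max(0, k - (n - l)):min(k, l)
  sum(dbinom(i, l, alpha) * dbinom(k - i, n - l, beta))
}

# chi-square goodness-of-fit p-value of integer draws against exact probs on
# 0..n, pooling cells with small expectation
gof_pvalue <- function(draws, probs) {
  n <- length(probs) - 1
  obs <- tabulate(draws + 1L, nbins = n + 1)
  keep <- probs * length(draws) >= 5
  # pool the sparse tail cells into one
  if (!all(keep)) {
    obs <- c(obs[keep], sum(obs[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  suppressWarnings(stats::chisq.test(obs, p = probs / sum(probs))$p.value)
}
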