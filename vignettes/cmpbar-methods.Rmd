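---
title: "Bounded count autoregression with exchangeable CMPB thinning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded count autoregression with exchangeable CMPB thinning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpbar)
```

## The problem

Many epidemiological and environmental series are counts with a hard upper
limit: the number of rainy days in a week (out of 7), the number of occupied
beds in a ward (out of `n`), the number of infected herds in a region. The
classical binomial AR(1) model treats the `n` units as independent, which
forces the marginal law to be binomial and the binomial index of dispersion

$$\mathrm{BID}(X) = \frac{n\,\mathrm{Var}(X)}{E(X)\,(n - E(X))}$$

to equal 1. Real bounded series are frequently over-dispersed (BID > 1;
dependent units that switch state together) or under-dispersed (BID < 1;
units that inhibit one another). `cmpbar` implements a bounded AR(1) whose
units are *exchangeable and dependent*, covering all three dispersion
regimes with a single extra parameter.

## The CMPB distribution

The building block is the Conway–Maxwell–Poisson-binomial law on
$\{0, \dots, n\}$:

$$P(X = x) = \frac{\binom{n}{x}^{\nu} \theta^{x}}{S(\theta, \nu)}, \qquad
S(\theta, \nu) = \sum_{x=0}^{n} \binom{n}{x}^{\nu} \theta^{x},$$

with odds parameter $\theta = \alpha/(1-\alpha) > 0$ and dispersion exponent
$\nu \in \mathbb{R}$. Three special cases anchor the interpretation:
$\nu = 1$ is exactly Binomial$(n, \alpha)$; $\nu = 0$ is the truncated
power-series (geometric-type) law $\theta^x / \sum_x \theta^x$; and as
$|\nu|$ grows the mass concentrates near the extremes ($\nu \to -\infty$:
the endpoints $0$ and $n$; $\nu \to +\infty$: the middle of the range). We
accept any finite $\nu$ — no narrower admissible range exists for the family
— and document that extreme values produce near-degenerate laws. The BID of
the family is $\ge 1$ when $\nu < 1$, exactly 1 at $\nu = 1$, and $\le 1$
when $\nu > 1$, which is what makes the model span all dispersion regimes.

Equivalently, the CMPB law is the distribution of the sum of $n$
*exchangeable* Bernoulli variables whose joint pmf depends on the
configuration only through its sum,
$P(z_1,\dots,z_n) \propto \binom{n}{x}^{\nu - 1}\theta^{x}$ with
$x = \sum z_i$. `dcmpb_joint()` exposes that law and the test suite
marginalizes it by full enumeration over $\{0,1\}^n$ as an independent
oracle for the pmf.

### Numerical choices

* Every normalizer, pmf and transition term is computed in the log domain
  with log-sum-exp; $\binom{n}{x}^\nu$ is evaluated as
  $\exp(\nu\,\texttt{lchoose}(n, x))$, since direct powers over- or
  underflow quickly for negative or large $\nu$.
* $\theta$ is the canonical parameter; $\alpha$ and $\lambda$
  ($\theta = \lambda^{\nu}$, defined for $\nu \ne 0$) are convenience
  constructors on `cmpb()`.
* Moments and BID are computed from the exact length-$(n+1)$ probability
  vector; the analytic route via the power-series derivatives $S'$, $S''$
  is retained (`cmpb_moments(, method = "series")`) purely as a
  cross-check — the two agree to $10^{-10}$ across the tested grid.
* The sampler is inverse-cdf through the one-term recurrence
  $P(X = x + 1) = \left(\frac{n - x}{x + 1}\right)^{\nu} \theta\, P(X = x)$,
  accumulating in the probability domain (the support is short) with the
  final cdf value clamped to 1, since rounding can leave it at
  $1 - 10^{-16}$.

## Thinning and the CMPBAR(1) process

The exchangeable CMPB thinning operator maps a count $x$ to the sum of $x$
exchangeable Bernoulli components, so conditionally on its argument the
result is $\mathrm{CMPB}(x, \alpha, \nu)$. `cmpb_thin()` therefore delegates
to the exact sampler with range $x$ — there is no need to simulate the
binary vector itself (though `cmpb_thin_vector()` does, for
pairwise-exchangeability checks). The process is

$$X_t = \alpha \diamond_\nu X_{t-1} + \beta \diamond_\nu (n - X_{t-1}),$$

survivors among the currently "on" units plus revivals among the "off"
units, the two thinnings independent given the past. The one-step
transition law is the convolution of $\mathrm{CMPB}(l, \theta_1, \nu)$ and
$\mathrm{CMPB}(n - l, \theta_2, \nu)$; every entry of the
$(n+1)\times(n+1)$ transition matrix is strictly positive, so the chain is
ergodic with a unique stationary law.

Two implementation decisions matter here:

* The textbook form of the transition probability sums
  $i = 0, \dots, \min\{k, l\}$, which formally includes terms whose
  binomial coefficient is zero; for $\nu \le 0$ those would be $0^{\nu}$.
  We restrict the sum to $\max(0, k - (n - l)) \le i \le \min(k, l)$ —
  exactly the terms that carry probability mass in the generative
  convolution. `cmpbar_transition()` evaluates that restricted sum in the
  log domain; `cmpbar_transition_matrix()` assembles rows by convolving the
  two component pmfs. The two routes agree to rounding and are
  cross-checked in the tests.
* The stationary law is computed exactly by a dense linear solve of
  $\pi P = \pi$ with the normalization row appended — no eigen-iteration
  tolerance, and cheap for the $n$ of interest (tens, not thousands). The
  marginal BID (`cmpbar_stationary_bid()`) therefore needs no simulation
  even though the marginal law has no closed form.

`cmpbar_simulate()` applies the two thinnings literally at each step via
precomputed per-state inverse cdfs. The generative model never specifies
the law of $X_0$; we default to an exact stationary draw with no burn-in
(an explicit integer start uses a 500-step burn-in instead). This choice
removes transient bias from the Monte-Carlo study and is our own; it is
documented rather than mandated by the model.

## Conditional maximum likelihood

The conditional log-likelihood given $X_0$ is
$\ell(\eta) = \sum_{t=1}^{T} \log P_\eta(X_t \mid X_{t-1})$ with
$\eta = (\theta_1, \theta_2, \nu)$. It depends on the data only through the
$(n+1)^2$ transition-pair counts, so each evaluation costs one transition
matrix regardless of $T$. `cmpbar_fit()` maximizes $\ell$ by BFGS in the
unconstrained coordinates $(\log\theta_1, \log\theta_2, \nu)$ with an
*analytic* gradient: differentiating a tilted pmf gives
$\partial p_i / \partial \log\theta = p_i (i - \mu)$ and
$\partial p_i / \partial \nu = p_i (c_i - \bar c)$ with
$c_i = \log\binom{n}{i}$, so each derivative of a transition row is again a
small convolution. The default start is the neutral binomial submodel:
$\nu = 1$ and $(\theta_1, \theta_2)$ from a moment fit using the sample
mean and lag-1 autocorrelation. A constant series is rejected as
non-identifiable; optimizer non-convergence triggers a small multi-start
fallback and is flagged on the result, never silent.

The asymptotic covariance follows the sandwich form
$J^{-1} I J^{-1} / T$: $\hat I$ is the average outer product of
per-transition scores (analytic), $\hat J$ the average per-transition
Hessian of $\log P_\eta$, obtained by central finite differences of the
analytic gradient (relative step $10^{-5}$, symmetrized). Under correct
specification $I = -J$ and the sandwich collapses to the observed-information
covariance $(-\hat J)^{-1}/T$, which is the default standard-error report
(`se = "hessian"`); the robust sandwich is one flag away. Which of the two a
published table of standard errors uses is usually unstated, which is why
both are first-class here. Near-flat $\nu$ directions are reported with a
condition-number warning rather than rejected, because identifiability
cannot be verified computationally.

The binomial AR(1) competitor (`bar1_fit()`) is the $\nu = 1$ submodel with
two free parameters, fitted in the $(\pi, \rho)$ parameterization with
$\alpha = \beta + \rho$, $\beta = (1 - \rho)\pi$ and the constraint
$\rho \in (\max\{-\pi/(1-\pi), -(1-\pi)/\pi\}, 1)$ handled by a logistic
transform. Model comparison uses $\mathrm{AIC} = 2k - 2\ell$ and
$\mathrm{BIC} = k \log T - 2\ell$ with $T$ = number of transitions (the
conditional likelihood conditions on $X_0$, so length $-\,1$ is the
effective sample size; the arithmetic of published three-parameter fits on
313-transition series is consistent with that convention).

## Diagnostics

Pearson residuals $r_t = (X_t - E[X_t|X_{t-1}]) / \sqrt{\mathrm{Var}(X_t|X_{t-1})}$
use the exact conditional moments. The PIT histogram is the
*non-randomized* (mean-PIT) construction for discrete data: each transition
contributes a linearly interpolated cdf segment between
$F(x_t - 1 \mid x_{t-1})$ and $F(x_t \mid x_{t-1})$, averaged across $t$ —
deterministic, unlike the randomized PIT. Ten bins is the default (the
convention in count-model practice; configurable), with a chi-square
uniformity summary and a Ljung–Box whiteness test on the residuals.

## The Monte-Carlo study and its scale

`sim_study()` reproduces the standard design: $n = 10$,
$T \in \{100, 300, 500\}$, twelve scenarios (`cmpbar_scenarios()`) crossing
$(\theta_1, \theta_2) \in \{(0.25, 0.25), (0.25, 1), (0.25, 1.5), (1, 1.5)\}$
with $\nu \in \{0.5, 1, 1.5\}$ — over-, equi- and under-dispersed regimes.
The headline spread column is deliberately the root mean squared deviation
about the *true* value with an $m - 1$ divisor,

$$sd = \sqrt{\tfrac{1}{m-1}\textstyle\sum_{i=1}^{m}(\hat\varphi_i - \varphi)^2},$$

an RMSE-like quantity rather than the about-the-mean standard deviation;
both are emitted (`mc_sd`, `mc_sd_about_mean`) so the distinction is never
hidden. Non-converged replications are dropped and counted, and a cell with
fewer than two converged fits is reported missing.

Replication seeds are spawned from the master seed by a counter, so results
are byte-reproducible and independent of worker scheduling
(`workers > 1` uses `parallel::mclapply`). The package's own acceptance runs
use 500 replications per cell of $T = 500$ series — a desk-scale study that
reproduces published Monte-Carlo means to within a few thousandths with
three-MC-standard-error agreement; full $m = 10{,}000$ replication is a
configuration change (`reps = 10000`), not a code change.

## What the synthetic data does and does not show

The packaged fixture (`inst/extdata/synthetic_rainy_days.csv`,
regenerable via `generate_fixture("rainy_days", T = 313, seed = 20230107)`)
is a *synthetic* stand-in emulating a weekly-rainy-days regime: $n = 7$,
$T = 313$ (six years of weeks), parameters
$(\theta_1, \theta_2, \nu) = (1.2313, 0.9547, 0.0995)$ — a strongly
over-dispersed, positively autocorrelated regime. Because it is simulated
from the model itself, passing recovery and calibration tests on it shows
correctness of the estimation and diagnostic machinery, not adequacy of the
model for real rainfall: real records carry seasonality, covariate effects,
measurement idiosyncrasies and possible non-stationarity that the generator
deliberately does not emulate. Analyses of real series should lean on the
PIT histogram, residual ACF and the BAR(1) comparison that the package
provides, not on the fixture results.

## Known limitations

* Marginal autocorrelation and forecasting distributions beyond one step
  are not provided as closed forms (users can take powers of the exact
  transition matrix).
* Beta-binomial and generalized-binomial AR competitors are out of scope;
  only the binomial AR(1) is fitted for comparison.
* The likelihood surface in $\nu$ can be flat when the data are close to
  equi-dispersed at small $T$; fits there are reported with a warning
  rather than suppressed.
* `n` is structural and must be supplied by the user; it is never inferred
  from the observed maximum.
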