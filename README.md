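# cmpbar

Bounded count time series — counts on a fixed range {0, …, n} such as rainy
days per week, occupied beds, infected herds — are usually modelled with the
binomial AR(1), which assumes the n units are independent and therefore
forces equi-dispersion: the binomial index of dispersion

    BID(X) = n · Var(X) / ( E(X) · (n − E(X)) )

equals 1 exactly. Real bounded series are routinely over-dispersed
(BID > 1) or under-dispersed (BID < 1). `cmpbar` implements a bounded AR(1)
whose counting units are **exchangeable and dependent**, built from the
Conway–Maxwell–Poisson-binomial (CMPB) distribution

    P(X = x) = C(n, x)^ν θ^x / S(θ, ν),      S(θ, ν) = Σ_x C(n, x)^ν θ^x,

with odds θ = α/(1 − α) and dispersion exponent ν (ν = 1 recovers the
binomial; ν < 1 over-disperses, ν > 1 under-disperses). The CMPBAR(1)
process combines two independent exchangeable CMPB thinnings —
survivors of the previous count plus revivals from its complement:

    X_t = α ⋄_ν X_{t−1} + β ⋄_ν (n − X_{t−1}).

The package provides, as tidyverse-friendly tibble-returning functions with
broom-style `tidy()`/`glance()` methods:

* exact CMPB pmf/cdf/moments/BID, an exact inverse-cdf sampler, and the
  exchangeable joint counting law (`cmpb()`, `dcmpb()`, `rcmpb()`,
  `cmpb_bid()`, `dcmpb_joint()`);
* CMPB and classical binomial thinning operators (`cmpb_thin()`,
  `binomial_thin()`);
* the exact transition matrix, stationary distribution, conditional
  moments/CBID and stationary BID of the CMPBAR(1) chain, plus a fast
  simulator (`cmpbar_transition_matrix()`, `cmpbar_stationary()`,
  `cmpbar_simulate()`);
* conditional maximum likelihood with analytic gradients,
  observed-information and sandwich standard errors, AIC/BIC, and the
  binomial AR(1) competitor fit (`cmpbar_fit()`, `bar1_fit()`);
* Pearson residual and non-randomized PIT diagnostics
  (`pearson_residuals()`, `pit_histogram()`, `cmpbar_diagnostics()`);
* a reproducible Monte-Carlo study driver (`sim_study()`) and a
  command-line interface (`inst/cli/cmpbar.R`).

## Worked example

The packaged fixture is a synthetic weekly-rainy-days-style series
(n = 7, T = 313) simulated from a strongly over-dispersed CMPBAR(1) regime:

```r
library(cmpbar)

path <- system.file("extdata", "synthetic_rainy_days.csv", package = "cmpbar")
y <- read_count_series(path, n = 7)

sample_bid(y)
#> [1] 2.0271          # > 1: extra-binomial variation

fit <- cmpbar_fit(y)
fit
#> CMPBAR fit by conditional maximum likelihood (n = 7, T = 312)
#>            theta1 theta2     nu
#> estimate   1.2645 0.9982 0.0751
#> std. error 0.0653 0.0596 0.0708
#> logLik -608.5252   AIC 1223.0504   BIC 1234.2794   converged: TRUE

dplyr::bind_rows(glance(fit), glance(bar1_fit(y)))
#> # A tibble: 2 × 7
#>   model  logLik   AIC   BIC  nobs converged iterations
#> 1 cmpbar  -609. 1223. 1234.   312 TRUE              24
#> 2 bar1    -676. 1355. 1363.   312 TRUE              71

cmpbar_diagnostics(y, fit)
#> Pearson residuals: mean -0.0017, variance 0.9869
#> Ljung-Box (lag 10): p = 0.6103
#> PIT uniformity (chi-square, 10 bins): p = 0.9458
```

Reading: the sample BID of 2.03 rules the equi-dispersed binomial AR(1)
out; the CMPBAR(1) fit recovers the generating parameters
(θ₁ = 1.2313, θ₂ = 0.9547, ν = 0.0995) within one to two standard errors,
with ν̂ ≈ 0.08 « 1 capturing the over-dispersion. The 132-point AIC gap
against the ν = 1 competitor quantifies how much the dependence between
units matters, and the residual/PIT diagnostics show the fitted model is
well calibrated on this series. `autoplot(pit_histogram(y, fit_params(fit)))`
draws the PIT bars; `series_acf(y)` gives the tidy ACF/PACF.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cmpbar.R", package = "cmpbar"))')
Rscript $CLI simulate --n 7 --theta1 1.23 --theta2 0.95 --nu 0.1 --T 313 --seed 1 -o series.csv
Rscript $CLI fit series.csv --n 7 --model cmpbar -o fit.json
Rscript $CLI diagnose series.csv fit.json -o report.json
Rscript $CLI bid --model --n 7 --theta1 1.23 --theta2 0.95 --nu 0.1
```
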