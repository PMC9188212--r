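# aftfirth

Firth-penalized accelerated failure time (AFT) models for small or heavily
censored right-censored survival data.

## The problem

Parametric AFT regression writes log survival time as

    log T = β'x + b·Z,

with `Z` a standard extreme-value, normal, or logistic variable — so that
`T` is Weibull, log-normal, or log-logistic. Maximum likelihood works well
at large samples, but with few subjects, heavy censoring (rare events), or
a strong binary covariate, the data can exhibit *separation / monotone
likelihood*: the likelihood increases monotonically in a coefficient, the
MLE runs to infinity, and Wald intervals become meaningless. Clinical
datasets with tens of patients and event rates below 20% hit this
routinely.

`aftfirth` is for biostatisticians and epidemiologists fitting parametric
survival models in exactly those settings. It maximizes the penalized
log-likelihood

    ℓ*(β, b) = ℓ(β, b) + ½ log |I(β, b)|,

where `I` is the (p+2)×(p+2) observed information including the scale —
the log of the Jeffreys invariant prior. The penalty removes the O(1/n)
bias of the MLE and guarantees finite estimates and standard errors even
under exact separation. Because penalization also shrinks the intercept
and scale (biasing survival predictions), a post-hoc correction
re-estimates `(β₀, b)` by plain ML with the penalized linear predictor
held fixed as an offset.

The package provides:

* `aft_mle()`, `aft_firth()`, `correct_intercept_scale()`, and the
  one-call wrappers `aft_fit()` / `aftreg()` (formula interface with
  `survival::Surv()` responses);
* analytic log-likelihood, score, and observed information
  (`aft_loglik()`, `aft_score()`, `aft_information()`), plus the penalty
  and modified score for verification;
* survival-probability and survival-time-quantile prediction;
* a separation / near-to-separation diagnostic (`classify_separation()`);
* a reproducible Monte Carlo study engine (`aft_scenario()`,
  `calibrate_lambda()`, `run_study()`) reporting bias, MSE, analytic and
  simulation SEs, and Wald CI widths for all three estimators;
* CSV in/out and a small CLI (`inst/cli/aftfirth.R`) with `fit`,
  `predict`, `diagnose`, and `simulate` subcommands.

## Worked example

```r
library(aftfirth)
set.seed(2026)

# a small Weibull study: n = 40, ~50% censoring
sc <- aft_scenario("weibull", n = 40, target_censoring = 0.5,
                   n_reps = 1, seed = 2026)
d <- simulate_aft_data(sc, calibrate_lambda(sc))

classify_separation(d, "xb")
#> Separation diagnostic for binary covariate 'xb'
#>          event
#> covariate  0  1
#>         0 10 12
#>         1  8 10
#> minimum cell count: 8
#> log-rank p-value: 0.1685
#> status: none

aft_fit(d, "weibull", method = "firth_corrected")
#> AFT model (extreme_value errors), method = firth_corrected
#> n = 40  events = 22
#>             Estimate     SE Lower 95 Upper 95
#> (Intercept)   2.9520 0.1419   2.6739   3.2302
#> xb            0.7431 0.2439   0.2650   1.2212
#> xc            0.6392 0.1307   0.3831   0.8953
#> scale         0.6633 0.1098   0.4480   0.8785
#> Penalized log-likelihood: -37.298
```

The generating truth here is β₀ = 3, β_b = 1.2 (binary `xb`), β_c = 0.7
(continuous `xc`), b = 0.67. The intercept (2.95), continuous slope
(0.64), and scale (0.66) land within one SE of truth; the binary slope
(0.74) sits about 1.9 SE below its true 1.2 — with 40 subjects and half of
them censored, a single dataset estimates a binary effect exactly this
noisily, which is the regime the Monte Carlo engine quantifies. Slope rows
come from the penalized fit; the intercept and scale rows are the
offset-model ML re-estimates, so predictions are not over-shrunk:

```r
fit <- aft_fit(d, "weibull", method = "firth_corrected")
predict_time_quantile(fit, x = c(1, 1, 0), q = 0.5)   # median, xb = 1
#> [1] 31.56538
predict_survival(fit, x = c(1, 1, 0), time = 50)
#> [1] 0.2498894
```

On separated data (a binary covariate aligned with event status)
`aft_mle()` reports non-convergence or coefficients beyond 10,
while `aft_firth()` returns finite estimates with finite SEs — that
contrast is the package's reason to exist, and is asserted in the test
suite.

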