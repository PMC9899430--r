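# ddvar

Density regulation does not only pull a population back towards its
carrying capacity — it also reshapes how strongly the population
fluctuates under environmental noise. `ddvar` is an R package for
quantifying that interaction in discrete-time population dynamics. It is
aimed at population ecologists and quantitative fisheries/wildlife
analysts who work with abundance time series and want to separate the
environmental and density-dependent components of population variability.

## The model in brief

On the log scale, the stochastic Gompertz model is an AR(1) process

```
y_t = r + β y_{t-1} + ε_t,    ε_t ~ N(0, σ²),    β = 1 − r/k,
```

with intrinsic growth rate `r`, log carrying capacity `k`, environmental
variance `σ²`, and density-dependence strength `β`. For `|β| < 1` the
stationary distribution is Normal with mean `μ∞ = r/(1−β) = k` and
variance

```
v∞ = σ² / (1 − β²).
```

The excess over the environmental variance, `σ²_dd = v∞ − σ² =
β²σ²/(1−β²)`, is the contribution of density regulation, and its share of
the stationary variance is simply

```
φ_dd = σ²_dd / v∞ = β².
```

So stronger density feedback means *larger*, not smaller, stationary
fluctuations, and the squared AR(1) coefficient is directly the
proportion of population variability attributable to density dependence.
The package provides these closed forms, seeded simulators for the
Gompertz and the (nonlinear) stochastic Ricker model, least-squares and
Bayesian MCMC fitting for both models with Gelman–Rubin diagnostics, and
a replicated simulation experiment that decomposes empirical stationary
variances using fitted environmental variances. See the vignette
(`vignettes/variance-decomposition.Rmd`) for the methods in full.

## Worked example

Simulate one trajectory from the design cell with strong density
feedback (`β = 0.6`) and moderate environmental noise, then decompose its
stationary variance using the fitted environmental variance:

```r
library(ddvar)

p <- gompertz_params(r = 0.4, k = 1, sigma2 = 0.10)
p
#> <gompertz_params> r = 0.4, k = 1, sigma2 = 0.1 (beta = 0.6)

decompose_analytic(p$beta, p$sigma2)
#> # A tibble: 1 × 4
#>   v_inf sigma2_env sigma2_dd phi_dd
#>   <dbl>      <dbl>     <dbl>  <dbl>
#> 1 0.156        0.1    0.0562   0.36

traj <- simulate_gompertz(p, n_steps = 300, seed = 1, n_discard = 200)
v <- empirical_stationary_variance(traj)   # 0.1314 for this seed

fit <- fit_gompertz_bayes(stationary_segment(traj), mcmc_settings(seed = 2))
tidy(fit)
#> # A tibble: 4 × 8
#>   term    mean     sd   q2.5 median q97.5  rhat    ess
#>   <chr>  <dbl>  <dbl>  <dbl>  <dbl> <dbl> <dbl>  <dbl>
#> 1 r      0.554 0.0994 0.357   0.552 0.751 1.00    480.
#> 2 beta   0.456 0.0911 0.274   0.457 0.636 1.00    476.
#> 3 sigma2 0.110 0.0161 0.0831  0.109 0.146 1.00  30000
#> 4 k      1.02  0.0650 0.888   1.02  1.15  1.000 11681.

decompose_empirical(v, posterior_mean(fit, "sigma2"))
#> # A tibble: 1 × 5
#>   v_inf sigma2_env sigma2_dd phi_dd negative
#>   <dbl>      <dbl>     <dbl>  <dbl> <lgl>
#> 1 0.131      0.110    0.0213  0.162 FALSE
```

Analytically, 36% of this cell's stationary variance is due to density
regulation (`φ_dd = β² = 0.36`). The single 100-point replicate above
estimates `φ_dd ≈ 0.16` — single short segments are noisy, which is why
the study design averages over replicated trajectories:

```r
cfg <- experiment_config(sigma2_grid = 0.10, r_grid = c(0.8, 0.6, 0.4),
                         n_replicates = 25, seed = 1)
records <- run_experiment(cfg)       # known-σ² + Gompertz + Ricker pathways
summarize_experiment(records)        # per-cell medians, quartiles, mean φ_dd vs β²
plot_phi_vs_beta(summarize_experiment(records))
```

The full reference design (σ² ∈ {0.10, 0.15, 0.20, 0.25}, β ∈ {0.2, 0.4,
0.6}, 100 replicates per cell) is simply `experiment_config()` with no
arguments. A command-line wrapper over the same functions is installed at
`system.file("cli", "ddvar.R", package = "ddvar")` with subcommands
`simulate`, `fit`, `decompose`, `experiment` and `summarize`.

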