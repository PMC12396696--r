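# gaitadapt

Estimation of retention factors and learning rates from stride-by-stride
joint-angle series recorded during locomotor adaptation experiments — the
setting where a walker tracks a knee-flexion target that jumps (here by +30°
after a 250-step baseline) and gradually adapts, possibly under reward or
punishment feedback. The package is aimed at movement scientists and
biostatisticians who want calibrated, reproducible estimates of *how much of
a movement carries over* and *how fast the movement adapts*, per feedback
group and over time.

## The models

For participant *i* in group *j* at stride step *t*, with group mean `m_jt`:

```
response:  y_ijt    = m_jt + e_ijt,          e_ijt ~ N(0, σ²_jt)
state:     y_ij,t+1 = A_j y_ijt + B_j m_jt
variance:  log σ²_jt = a_j log σ²_j,t−1 + u_jt,   u_jt ~ N(0, σ²_u)
```

`A_j` is the retention factor (carry-over, near 1), `B_j` the learning rate.
Two independent estimation tracks are implemented:

1. **Sequential track** — a dynamically weighted particle filter
   (`run_filter()`): per-step Gibbs draws of `m_jt` from their Normal full
   conditionals embedded in a particle filter over the stochastic
   log-variance state, with split/prune weight control. Constant rates are
   then estimated by constrained Gaussian ML regression of the state model
   (`fit_state_model()`), with nested χ²-difference tests of group equality
   (`lr_difference_test()`).
2. **Functional track** — a Bayesian cubic P-spline fit of each group's mean
   function by Gibbs sampling (`gibbs_fda()`, truncated-power basis, K = 19
   knots, diagonal penalty sparing the global cubic). Posterior draws of the
   curve and its first difference yield time-varying rate functions
   `A_j(t) = f̂′_j(t)` and `B_j(t) = (ȳ_j,t+1 − f̂′_j(t))/f̂_j(t)` with
   pointwise 95% credible bands (`rate_functions()`), and a per-step
   band-overlap comparison between groups (`band_overlap()`).

A synthetic cohort generator (`generate_cohort()`) reproduces the study
design (3 groups × 11 participants × 500 steps) with known ground truth, so
every stage is testable without the original data. See the methods vignette
(`vignettes/locomotor-adaptation-methods.Rmd`) for the full model account,
design decisions and validation protocols.

## Worked example

```r
library(gaitadapt)

trials <- generate_cohort(synth_config(seed = 42))   # 3 x 11 x 500 cohort
adj    <- baseline_adjust(trials)                    # remove participant baselines

fe  <- run_filter(adj, n_particles = 2000, n_min = 1000, n_max = 4000, seed = 43)
fit <- fit_state_model(adj, driver_series(adj, "filter", filter = fe))
fit
#> State-model rate fit (level = individual, driver = filter, constrain = none)
#> -2 log-likelihood: 55425.956 on 6 coefficient(s)
#> # A tibble: 6 × 4
#>   group      term  estimate std.error
#>   <chr>      <chr>    <dbl>     <dbl>
#> 1 Control    A       0.967    0.00379
#> 2 Punishment A       0.955    0.00428
#> 3 Reward     A       0.878    0.00702
#> 4 Control    B       0.0360   0.00387
#> 5 Punishment B       0.0489   0.00447
#> 6 Reward     B       0.126    0.00723
```

The cohort was generated with true retention `(0.96, 0.95, 0.88)` and true
learning rates `(0.04, 0.05, 0.12)` for Control/Punishment/Reward: the fits
recover both, with the Reward group retaining least and learning fastest.
Testing whether the learning rates differ between groups:

```r
eqB <- fit_state_model(adj, driver_series(adj, "filter", filter = fe),
                       constrain = "B")
lr_difference_test(fit, eqB)
#> # A tibble: 1 × 3
#>   chi2_diff    df  p_value
#>       <dbl> <int>    <dbl>
#> 1      121.     2 6.75e-27
```

The equality of learning rates is rejected (χ² difference ≈ 121 on 2 df).
The functional track gives the same story over time — on raw angles, since
the rate-function denominator is the fitted curve level:

```r
post <- gibbs_fda(trials, spline_model(500), S = 1000, burn_in = 1000, seed = 44)
tv   <- rate_functions(post)
dplyr::filter(tibble::as_tibble(tv), step %in% c(100, 260, 400), group == "Reward")
#> # A tibble: 3 × 12
#>   group   step     f  f_lo  f_hi       A    A_lo    A_hi     B  B_lo  B_hi B_ok
#>   <chr>  <int> <dbl> <dbl> <dbl>   <dbl>   <dbl>   <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 Reward   100  60.0  59.5  60.4 -0.0497 -0.0658 -0.0345 0.993 0.986  1.00 TRUE
#> 2 Reward   260  77.2  76.8  78.1  1.15    1.11    1.20   1.05  1.04   1.06 TRUE
#> 3 Reward   400  91.8  91.1  92.3 -0.0920 -0.114  -0.0746 1.00  0.998  1.01 TRUE
```

`A(t)` (degrees/step) is near zero during steady phases and peaks in the
post-jump transient (step 260); the fitted curve `f` climbs from the 60°
baseline to the 90° target. `autoplot()` methods draw the trajectories,
filter bands and rate functions; `run_compare()` chains every stage
(simulate/read → filter → regressions → spline track → band overlap) and
writes tidy CSV artifacts.

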