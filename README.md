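# ncctrends

Simulation and analysis of platform trials that use **non-concurrent
controls** with model-based **time-trend adjustment**.

## The problem

In a platform trial, experimental arms enter and leave over time while
sharing one control arm. When an arm (here: arm 2) joins after `N1`
patients, the control data split into *non-concurrent* controls (randomised
before arm 2 existed) and *concurrent* controls. Re-using the
non-concurrent controls makes the arm-2 comparison more precise — but any
drift in the outcome level over calendar time (changing standard of care,
population shift, expectation effects) biases a naive pooled comparison,
because arm 2 recruits late while much of the pooled control is early.

`ncctrends` is for trial statisticians who want to quantify that trade-off.
It provides:

* the two-period platform **design** and permuted-block / simple
  randomisation (`trial_design()`, `allocate()`);
* configurable **time trends** — linear, step-wise, inverted-U — with
  arm-specific strengths (`trend_spec()`);
* a **data generator** for continuous and binary endpoints from
  `g(E(Y_j)) = eta0 + theta_k I(k_j = k) + f(t_j)` (`scenario_spec()`,
  `simulate_trial()`, `expected_cell_means()`);
* the **analysis methods**: regression with a step-function or linear time
  adjustment fitted on all arms (with or without an arm-1-by-period
  interaction) or on control + arm 2 only, plus the unadjusted pooled and
  separate (concurrent-only) comparisons, each giving a one-sided test of
  `H02: theta2 <= 0` (`fit_model()`, `fit_models()`);
* the **closed form** of the step-adjusted estimator as a weighted sum of
  cell means,

      theta2~ = (ybar22 - ybar02) + rho [(ybar11 - ybar01) - (ybar12 - ybar02)],
      rho     = (1/n02) / (1/n01 + 1/n11 + 1/n02 + 1/n12),

  where `rho` is both the weight of the non-concurrent-control information
  and the fractional variance reduction of the model-based period-2
  control estimate (`ncc_rho()`, `ncc_weights()`, `theta2_weighted()`,
  `control_estimate_period2()`, `variance_reduction()`, `power_pooled()`);
* a replicate **simulation engine** for operating characteristics — type-1
  error, power, bias, RMSE with Monte-Carlo standard errors — over scenario
  grids (`run_scenario()`, `run_grid()`, `scenario_grid()`), plus YAML run
  configurations and a command-line front end (`inst/cli/ncct` with
  subcommands `simulate`, `analyse`, `run`, `plot`).

## Worked example

The reference design has 125 control and 125 arm-1 patients per period and
250 arm-2 patients in period 2. Its weight matrix shows how the
step-adjusted estimator uses every cell:

```r
library(ncctrends)
design <- trial_design(rbind(c(125, 125),
                             c(125, 125),
                             c(0,   250)))
ncc_weights(design$n)
#> Weighted-means representation, rho = 0.25
#>      period1 period2
#> arm0   -0.25   -0.75
#> arm1    0.25   -0.25
#> arm2    0.00    1.00
```

`rho = 0.25`: a quarter of the weight on the period-2 control estimate
comes from the non-concurrent data, and its variance is 25% lower than the
concurrent-control mean's. Now simulate one trial with a step trend of
0.15 in every arm and effects `theta1 = theta2 = 0.25` (calibrated so the
pooled test has 80% power: `power_pooled("continuous", 250, delta = 0.25)`
gives 0.797), and fit four methods:

```r
scenario <- scenario_spec(design, trend_spec("step", 0.15), "continuous",
                          theta = c(0.25, 0.25))
trial <- simulate_trial(scenario, seed = 2026)
fit_models(trial, c("ALLTC_step", "ALLTCI_step", "pooled", "separate"))
#>        method estimate     se  df  p_value reject converged n_used
#> 1  ALLTC_step    0.208 0.0991 746 0.017911   TRUE      TRUE    750
#> 2 ALLTCI_step    0.131 0.1084 745 0.113595  FALSE      TRUE    750
#> 3      pooled    0.288 0.0896 498 0.000706   TRUE      TRUE    500
#> 4    separate    0.131 0.1099 373 0.117072  FALSE      TRUE    375
```

On this replicate the step-adjusted model (`ALLTC_step`) rejects with a
smaller standard error than the separate analysis; the pooled estimate is
upward-biased because it ignores the trend (it absorbs part of the 0.15
drift into the treatment effect). The interaction model (`ALLTCI_step`)
reproduces the separate point estimate exactly — non-concurrent controls do
not contribute to it. Operating characteristics over 2,000 replicates make
the power gain visible:

```r
run_scenario(scenario, c("ALLTC_step", "separate"),
             n_reps = 2000, base_seed = 2026)
#>       method reject_rate     bias   rmse
#> 1 ALLTC_step       0.717 3.73e-04 0.0997
#> 2   separate       0.646 4.47e-05 0.1084
```

Both methods are unbiased under equal trends, and the step-adjusted model
converts the non-concurrent controls into roughly seven points of power
and a smaller RMSE. The same machinery runs from the shell:

```sh
inst/cli/ncct run --config my_scenarios.yaml --reps 10000 --seed 42 --out oc.csv
inst/cli/ncct plot --results oc.csv --out rejection_curves.pdf
```

See `vignettes/time-trend-adjustment.Rmd` for the models, the derivation
and verification of `rho`, the generator's default study conditions, and
the package's numerical and design choices.

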