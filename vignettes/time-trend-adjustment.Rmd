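---
title: "Time-trend adjustment with non-concurrent controls: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-trend adjustment with non-concurrent controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncctrends)
```

## The setting

A platform trial starts with a control arm (arm 0) and one experimental arm
(arm 1). After `N1` patients, a second experimental arm (arm 2) enters; the
trial then runs for `N2` further patients. Controls randomised before arm 2
entered are *non-concurrent* with respect to arm 2; controls randomised
afterwards are *concurrent*. Using the non-concurrent controls in the
comparison of arm 2 versus control increases precision — but if the outcome
level drifts over calendar time (changing standard of care, population
drift, seasonal or expectation effects), a naive pooled comparison is
biased, because all of arm 2's patients are late and a disproportionate
share of the pooled controls are early.

`ncctrends` implements the model-based remedy: regression adjustment for
time, stratified by *period* (the spans between arms entering or leaving),
together with a simulator to quantify when the adjustment works and how
badly it fails when its assumptions are violated.

## Models

Outcomes follow a generalised linear model on the link scale `g` (identity
for continuous endpoints with iid normal errors of SD `sigma`; logit for
binary endpoints). The data-generating model used by the simulator is

    g(E(Y_j)) = eta0 + theta_k I(k_j = k) + f(t_j),

where `j = 1..N` indexes patients in enrolment order, `k_j` is the arm of
patient `j`, and `f` is a time-trend function shared or arm-specific. The
analysis methods are:

* **ALLTC_step** — `g(E(Y_j)) = eta0 + theta1 I(k=1) + theta2 I(k=2) +
  nu I(j > N1)`, fitted on all arms. The period indicator absorbs any
  between-period shift that is *equal across arms and additive on the model
  scale*.
* **ALLTCI_step** — adds an arm-1-by-period interaction, freeing arm 1 to
  have its own trend.
* **TC_step** — the same step adjustment fitted on control and arm 2 only.
* **ALLTC_linear / ALLTCI_linear / TC_linear** — the period indicator
  replaced by a linear term `gamma * j` (patients are assumed to arrive at
  a uniform pace, so the enrolment index is proportional to calendar time).
* **pooled / separate** — no time adjustment: arm 2 against all controls,
  or against concurrent controls only.

All methods test the one-sided null `H02: theta2 <= 0` at level
`alpha = 0.025` by default (t-test on the residual degrees of freedom for
continuous endpoints, Wald z-test for binary).

## The closed-form representation

For continuous endpoints, the `ALLTC_step` least-squares estimate of
`theta2` is a weighted sum of the six arm-by-period cell means with a
single free weight,

    theta2~ = (ybar22 - ybar02) + rho * [(ybar11 - ybar01) - (ybar12 - ybar02)],

where, writing `n_{k,s}` for the cell counts,

    rho = (1/n02) / (1/n01 + 1/n11 + 1/n02 + 1/n12).

`rho` is the weight the model places on the non-concurrent-control
information: the estimator replaces the concurrent-control mean by

    y02~ = (1 - rho) * ybar02 + rho * [ybar01 + (ybar12 - ybar11)],

the period-1 control mean carried forward by arm 1's observed
between-period shift. Its variance is `(1 - rho)` times that of `ybar02`,
so `rho` is also the fractional variance reduction bought by the
non-concurrent controls. At the reference design (125 patients per
control/arm-1 cell, 250 in arm 2) `rho = 0.25`.

The general `rho` expression is not taken on trust: the test suite
re-derives it, for random cell counts, from the row of the least-squares
projector `e' (X'X)^{-1} X'` that produces the arm-2 coefficient, whose
entries are constant within cells and sum to the cell weights. The
closed-form and the brute-force weights agree to `1e-10`; had they not,
the least-squares solution would have been authoritative.

```{r rho}
ncc_rho(125, 125, 125, 125)
ncc_weights(rbind(c(125, 125), c(125, 125), c(0, 250)))
```

## Time-trend patterns

Three shapes are built in, parameterised by a per-arm strength `lambda` on
the model scale and evaluated at the enrolment index:

* linear: `lambda * (j - 1)/(N - 1)`;
* step: `lambda * I(j > N1)`;
* inverse-U: `lambda * (j - 1)/(N - 1) * (I(j <= Np) - I(j > Np))`, with
  turning point `Np` at `N1/2`, `N1`, `N1 + N2/2` (default) or any index.

The inverse-U form flips the *sign of the whole term* at the turning
point, so it has a jump discontinuity at `Np`. We implement it exactly in
that form, since it is the reference shape for the trend-misspecification
experiments; whether one would prefer a continuous peak in practice is a
modelling question, so a continuous "tent" variant with the same peak and
slope is available behind `inverse_u_continuous = TRUE`, but it is never
the default. Negative `lambda` yields the corresponding U shape.

Entry times are fixed at `t_j = j` by default. A `entry = "random"` mode
replaces them by `N` sorted uniform draws on `[1, N]` in the smooth
patterns (the step pattern keeps the enrolment-index period indicator);
the exact distribution of staggered entry is a stand-in choice, and
results are insensitive to it in our checks.

## What the generator emulates — and what it does not

The generator's defaults are the study conditions of the
operating-characteristics experiments: the two-period design
`n = (125, 125 | 125, 125 | 0, 250)` (so `N1 = 250`, `N = 750`), residual
SD `sigma = 1` with control mean `eta0 = 0` and effects
`theta1 = theta2 = 0.25` for continuous endpoints; control rate
`p0 = 0.7` with odds ratios `OR = 1.8` (benefit) or `0.4` (harm) and
`OR2 = 1.8` under the alternative for binary endpoints; trend strengths
`lambda = 0.15` (equal-trend checks) or `lambda0 = lambda2 = 0.1`
(continuous sweeps) and `0.25` (binary sweeps). These effect sizes are
calibrated so that the pooled test of two groups of 250 has 80% power at
one-sided 2.5% — `power_pooled()` reproduces this analytically.

Allocation is permuted-block with block sizes 4 (period 1, 1:1) and 12
(period 2, 2:1:1). Because the printed ratio "2:1:1" is ambiguous about
which arm is doubled, the block composition is fixed from the sample sizes:
control 3, arm 1 3, arm 2 6 per block of 12. Period sizes are not
multiples of the block sizes (250/4, 500/12); we fill complete blocks and
close each period with a truncated block that is a random permutation of
exactly the residual per-arm counts. This keeps realised cell counts equal
to the design — which the closed-form algebra assumes — at the cost of a
slightly constrained final block. "Simple" randomisation is likewise
implemented conditionally on the final counts (a random permutation of the
period's arm-label multiset); an unconditional Bernoulli mode
(`conditional = FALSE`) exists to illustrate what unrestricted allocation
does to the residual-variance structure.

The simulator emulates *only* the features the models address: a shared
smooth or step drift, arm-specific drifts, and the two endpoint families.
It does not generate covariates, missing data, intercurrent events,
staggered outcome ascertainment, interim looks, or time-to-event outcomes.
Passing tests therefore show that the estimators behave as the theory
predicts *under the stated data-generating model*; they say nothing about
robustness to, e.g., informative dropout in a real platform trial.

## Numerical choices

* Continuous fits use least squares via the QR decomposition with the
  classical covariance; binary fits use IRLS (`stats::glm.fit`) with
  convergence tolerance `1e-8` and at most 50 iterations, and Wald
  inference. Whether the original analyses used Wald or likelihood-ratio
  tests is not determinable; Wald is the conventional default and is what
  we document and test.
* Non-convergence and (quasi-)separation — flagged when IRLS fails or the
  arm-2 Wald SE exceeds 100 on the log-odds scale — yield a `converged =
  FALSE` result with `NA` estimate, never a silent number. The simulation
  engine excludes such replicates from summaries and reports their count
  (`n_converged`); at the reference design they essentially never occur.
* A dataset with constant outcomes gives a zero effect estimate with zero
  residual variance; the estimate is returned and the untestable p-value
  is `NA`.
* The continuous `pooled`/`separate` tests are pooled-SD two-sample
  t-tests (equivalently OLS on a treatment indicator), matching the 80%
  power calibration; Welch is available behind `var_equal = FALSE`. Binary
  `pooled`/`separate` use logistic regression with a treatment factor; the
  closed-form two-proportion z-test lives only in `power_pooled()`, where
  both the unpooled-variance (default) and pooled-variance critical-value
  variants are exposed because the naming convention is ambiguous — they
  agree to well under a percentage point here.
* The linear-time models use the raw index `j` as regressor; centring
  would change only the intercept, not the arm-2 estimate.
* Replicate `r` of a simulation uses the `r`-th of `n_reps` seeds drawn
  once from the base seed, so runs are deterministic, replicates are
  independent units, and execution order is irrelevant. All methods are
  fitted to the same replicate datasets (paired comparisons).

## Problem sizes in the test suite

The operating-characteristics experiments in the test suite use 10,000
replicates for level and power statements (Monte-Carlo SE of a rejection
rate near 0.025 is about 0.0016; assertions allow 3 MC SEs) and 4,000
replicates for the qualitative monotonicity and ordering checks in the
unequal-trend sweeps, whose effects are an order of magnitude larger than
the corresponding MC noise. The arm-1 sweep grid
`lambda1 = 0, 0.05, 0.1, 0.15, 0.2` against `lambda0 = lambda2 = 0.1`
(continuous) and the matched-deficit pair `lambda1 = -0.25` against
`lambda0 = lambda2 = 0.25` (binary, OR1 = 1.8 vs 0.4) are our choices:
the sweep grids behind the original figures are not printed, and the
binary deficit is chosen large enough that the predicted ordering of the
two inflations is resolvable above Monte-Carlo noise at 4,000 replicates.

## Known limitations

* The closed-form weights cover the canonical two-period, three-arm
  layout; designs with more periods or arms are handled numerically by
  the regression fits (the period term becomes a factor with `S - 1`
  contrasts), but no closed-form `rho` is reported for them.
* Type-1-error control of the step-adjusted *linear* model under smooth
  trends relies on block randomisation; under unconditional simple
  randomisation the per-period residual variances differ and the pooled
  variance estimate can be biased. The heteroscedastic per-period
  variance model that would repair this is not implemented.
* Bayesian borrowing approaches, randomisation tests and interim analyses
  are out of scope.
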