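test_that("rho has the stated closed form and reduces correctly under equal allocation", {
  expect_equal(ncc_rho(125, 125, 125, 125), 0.25)
  expect_equal(ncc_rho(100, 50, 200, 25), 1 / 15)
  # equal control/arm-1 allocation per period: half the NCC proportion
  for (n1 in c(10, 80, 125, 400)) {
    for (n2 in c(25, 125, 600)) {
      expect_equal(ncc_rho(n1, n1, n2, n2), 0.5 * n1 / (n1 + n2))
      expect_lt(ncc_rho(n1, n1, n2, n2), 0.5)
    }
  }
  expect_error(ncc_rho(0, 10, 10, 10), ">= 1")
})

test_that("rho matches a brute-force least-squares oracle", {
  # the general formula is only trusted because it reproduces, for random
  # cell counts, the weight that the step-function OLS fit implicitly
  # places on the between-period arm-1 contrast
  set.seed(501)
  for (i in 1:25) {
    n <- random_counts()
    means <- matrix(rnorm(6), 3, 2)
    dat <- dataset_from_counts(n, means, sd = 0.5)
    X <- cbind(1, dat$arm == 1, dat$arm == 2, dat$period == 2)
    a <- solve(crossprod(X), t(X))[3, ]  # row extracting theta2-hat
    # cell weights implied by OLS: a_j is constant within a cell
    w11 <- sum(a[dat$arm == 1 & dat$period == 1])
    expect_equal(w11, ncc_rho(n[1, 1], n[2, 1], n[1, 2], n[2, 2]),
                 tolerance = 1e-10)
    # full weight matrix recovered the same way
    w <- sapply(1:2, function(s) sapply(0:2, function(k) {
      sum(a[dat$arm == k & dat$period == s])
    }))
    expect_equal(unname(w), unname(ncc_weights(n)$w), tolerance = 1e-10)
  }
})

test_that("rho limits: many concurrent controls kill the weight, many NCC saturate it", {
  expect_lt(ncc_rho(125, 125, 1e9, 125), 1e-6)
  expect_gt(ncc_rho(1e9, 1e9, 125, 1e9), 1 - 1e-6)
  # monotone: increasing in n01, n11, n12; decreasing in n02
  set.seed(61)
  for (i in 1:20) {
    n <- pmax(1, rpois(4, 50))
    base <- ncc_rho(n[1], n[2], n[3], n[4])
    expect_gt(ncc_rho(n[1] + 5, n[2], n[3], n[4]), base)
    expect_gt(ncc_rho(n[1], n[2] + 5, n[3], n[4]), base)
    expect_gt(ncc_rho(n[1], n[2], n[3], n[4] + 5), base)
    expect_lt(ncc_rho(n[1], n[2], n[3] + 5, n[4]), base)
  }
})

test_that("weight matrices satisfy their structural invariants", {
  # equal cells: the worked example
  n <- rbind(c(125, 125), c(125, 125), c(0, 250))
  w <- ncc_weights(n)
  expect_equal(unname(w$w),
               rbind(c(-0.25, -0.75), c(0.25, -0.25), c(0, 1)))
  set.seed(71)
  for (i in 1:20) {
    nn <- random_counts()
    ww <- ncc_weights(nn)
    expect_equal(sum(ww$w), 0)
    expect_equal(ww$w[["arm2", "period2"]], 1)
    expect_equal(ww$w[["arm2", "period1"]], 0)
    expect_equal(ww$w[["arm0", "period2"]], -(1 - ww$rho))
    expect_true(ww$rho > 0 && ww$rho < 1)
  }
  expect_error(ncc_weights(rbind(c(5, 5), c(5, 5), c(2, 5))), "n21 = 0")
})

test_that("theta2_weighted reproduces hand arithmetic and collapses on flat data", {
  n <- rbind(c(125, 125), c(125, 125), c(0, 250))
  flat <- matrix(0.3, 3, 2)
  expect_equal(theta2_weighted(flat, n), 0)
  # equal-trends truth: control (0, 0.1), arm1 (0.25, 0.35), arm2 0.35
  m <- rbind(c(0, 0.1), c(0.25, 0.35), c(NA, 0.35))
  expect_equal(theta2_weighted(m, n), 0.25)
})

test_that("control_estimate_period2 satisfies its identities", {
  n <- rbind(c(125, 125), c(125, 125), c(0, 250))
  m <- rbind(c(0, 0.1), c(0.25, 0.35), c(NA, 0.35))
  expect_equal(control_estimate_period2(m, n), 0.1)
  set.seed(81)
  for (i in 1:20) {
    nn <- random_counts()
    mm <- matrix(rnorm(6), 3, 2)
    # theta2~ = ybar22 - y02~
    expect_equal(mm[3, 2] - control_estimate_period2(mm, nn),
                 theta2_weighted(mm, nn))
  }
  # rho -> 0: the concurrent-only estimate
  m0 <- rbind(c(0.1, 0.6), c(0.7, 0.2), c(NA, 0.9))
  n0 <- rbind(c(2, 10000000), c(2, 2), c(0, 10))
  expect_equal(control_estimate_period2(m0, n0), 0.6, tolerance = 1e-5)
})

test_that("the variance-reduction identity holds in Monte Carlo", {
  # draw independent cell means at their sampling distribution and compare
  # the empirical variance ratio of the two period-2 control estimates
  n <- rbind(c(125, 125), c(125, 125), c(0, 250))
  rho <- ncc_rho(125, 125, 125, 125)
  expect_equal(variance_reduction(125, 125, 125, 125), 0.25)
  set.seed(91)
  R <- 20000L
  draws <- vapply(seq_len(R), function(r) {
    m <- matrix(rnorm(6, 0, sqrt(1 / c(n[1:2, 1], 1, n[1:2, 2], n[3, 2]))), 3, 2)
    c(tilde = control_estimate_period2(m, n), bar = m[1, 2])
  }, numeric(2))
  ratio <- var(draws["tilde", ]) / var(draws["bar", ])
  # variance-ratio MC error: batch SE over 20 batches
  batches <- split(seq_len(R), rep(1:20, each = R / 20))
  bratio <- vapply(batches, function(ix) {
    var(draws["tilde", ix]) / var(draws["bar", ix])
  }, numeric(1))
  se <- sd(bratio) / sqrt(length(bratio))
  expect_lt(abs(ratio - (1 - rho)), 3 * se)
})

test_that("analytic power calibrations land at their design values", {
  expect_equal(power_pooled("continuous", 250, delta = 0.25, sigma = 1,
                            alpha = 0.025), 0.80, tolerance = 0.01)
  expect_equal(power_pooled("binary", 250, p0 = 0.7, OR = 1.8,
                            alpha = 0.025), 0.80, tolerance = 0.01)
  expect_equal(power_pooled("binary", 250, p0 = 0.7, OR = 1.8,
                            alpha = 0.025, variance = "pooled"),
               0.80, tolerance = 0.01)
  # null effects give power = alpha
  expect_equal(power_pooled("continuous", 100, delta = 0, alpha = 0.025), 0.025)
  expect_equal(power_pooled("binary", 100, p0 = 0.6, OR = 1, alpha = 0.05),
               0.05, tolerance = 1e-10)
  expect_error(power_pooled("binary", 100, p0 = 1.5, OR = 2), "p0")
})
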