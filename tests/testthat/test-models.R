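test_that("ALLTC_step equals the closed-form weighted-means estimate", {
  set.seed(101)
  for (i in 1:50) {
    n <- random_counts()
    dat <- dataset_from_counts(n, matrix(rnorm(6), 3, 2))
    f <- fit_model(dat, "ALLTC_step")
    cs <- cell_stats(dat)
    expect_equal(f$estimate, theta2_weighted(cs$means, cs$counts),
                 tolerance = 1e-10)
  }
})

test_that("interaction and treatment-control models use concurrent controls only", {
  set.seed(102)
  for (i in 1:20) {
    n <- random_counts()
    dat <- dataset_from_counts(n, matrix(rnorm(6), 3, 2))
    cs <- cell_stats(dat)
    sep <- cs$means[3, 2] - cs$means[1, 2]
    expect_equal(fit_model(dat, "ALLTCI_step")$estimate, sep, tolerance = 1e-10)
    expect_equal(fit_model(dat, "TC_step")$estimate, sep, tolerance = 1e-10)
    expect_equal(fit_model(dat, "separate")$estimate, sep, tolerance = 1e-10)
  }
})

test_that("continuous fits agree with lm() and the pooled test with t.test()", {
  d <- small_design()
  sc <- scenario_spec(d, trend_spec("linear", 0.2), "continuous",
                      theta = c(0.25, 0.1))
  dat <- simulate_trial(sc, seed = 17)
  ref <- lm(y ~ factor(arm) + I(period == 2), data = dat)
  f <- fit_model(dat, "ALLTC_step")
  sref <- summary(ref)$coefficients["factor(arm)2", ]
  expect_equal(f$estimate, unname(coef(ref)["factor(arm)2"]))
  expect_equal(f$se, unname(sref["Std. Error"]))
  expect_equal(f$df, df.residual(ref))

  reflin <- lm(y ~ factor(arm) + j, data = dat)
  flin <- fit_model(dat, "ALLTC_linear")
  expect_equal(flin$estimate, unname(coef(reflin)["factor(arm)2"]))
  expect_equal(flin$se,
               unname(summary(reflin)$coefficients["factor(arm)2", "Std. Error"]))

  refint <- lm(y ~ factor(arm) + j + I(j * (arm == 1)), data = dat)
  fint <- fit_model(dat, "ALLTCI_linear")
  expect_equal(fint$estimate, unname(coef(refint)["factor(arm)2"]))

  tt <- t.test(dat$y[dat$arm == 2], dat$y[dat$arm == 0],
               alternative = "greater", var.equal = TRUE)
  fp <- fit_model(dat, "pooled")
  expect_equal(fp$estimate, unname(diff(rev(tt$estimate))))
  expect_equal(fp$p_value, tt$p.value)
  # Welch variant behind the flag
  fw <- fit_model(dat, "pooled", var_equal = FALSE)
  tw <- t.test(dat$y[dat$arm == 2], dat$y[dat$arm == 0],
               alternative = "greater")
  expect_equal(fw$p_value, tw$p.value)
})

test_that("logistic fits agree with glm() and recover parameters at large n", {
  d <- small_design()
  sc <- scenario_spec(d, trend_spec("step", 0.25), "binary",
                      p0 = 0.6, OR = c(1.5, 1.5))
  dat <- simulate_trial(sc, seed = 23)
  ref <- glm(y ~ factor(arm) + I(period == 2), family = binomial, data = dat)
  f <- fit_model(dat, "ALLTC_step")
  expect_equal(f$estimate, unname(coef(ref)["factor(arm)2"]), tolerance = 1e-7)
  expect_equal(f$se,
               unname(summary(ref)$coefficients["factor(arm)2", "Std. Error"]),
               tolerance = 1e-7)
  expect_equal(f$df, Inf)

  # parameter recovery at 10^5 per cell, within 3 SEs
  big <- trial_design(rbind(c(1e5, 1e5), c(1e5, 1e5), c(0, 1e5)))
  scb <- scenario_spec(big, trend_spec("step", 0.25), "binary",
                       p0 = 0.7, OR = c(1.8, 1.3),
                       randomisation = list(method = "simple"))
  datb <- simulate_trial(scb, seed = 29)
  fb <- fit_model(datb, "ALLTC_step")
  truth <- c(qlogis(0.7), log(1.8), log(1.3), 0.25)
  ses <- sqrt(diag(fb$vcov))[names(fb$coefficients)]
  expect_true(all(abs(unname(fb$coefficients) - truth) < 3 * ses))
})

test_that("degenerate and malformed inputs fail loudly, constants give zero", {
  d <- small_design()
  sc <- scenario_spec(d, trend_spec("step", 0), "continuous", theta = c(0, 0))
  dat <- simulate_trial(sc, seed = 3)
  dat$y <- 1  # constant outcome: every estimate is exactly 0
  for (m in c("ALLTC_step", "ALLTCI_step", "TC_step", "ALLTC_linear",
              "pooled", "separate")) {
    expect_equal(fit_model(dat, m)$estimate, 0)
  }
  no2 <- dat[dat$arm != 2, ]
  expect_error(fit_model(no2, "ALLTC_step"), "arm 2")
  no1 <- dat[dat$arm != 1, ]
  expect_error(fit_model(no1, "ALLTC_step"), "all arms")
  expect_silent(fit_model(no1, "TC_step"))
  expect_error(fit_model(dat, "ALLTC_step", alpha = 0.7), "alpha")
})

test_that("separation is reported as non-convergence, never a silent estimate", {
  d <- trial_design(rbind(c(6, 6), c(6, 6), c(0, 12)))
  sc <- scenario_spec(d, trend_spec("step", 0), "binary", p0 = 0.5,
                      OR = c(1, 1))
  dat <- simulate_trial(sc, seed = 5)
  dat$y <- as.integer(dat$arm == 2)  # perfectly separated
  f <- fit_model(dat, "ALLTC_step", endpoint = "binary")
  expect_false(f$converged)
  expect_true(is.na(f$estimate))
  expect_true(is.na(f$reject))
})

test_that("one_sided_p encodes the upper-tail convention", {
  expect_equal(one_sided_p(0, 1), 0.5)
  expect_equal(one_sided_p(0, 2.5, df = 17), 0.5)
  expect_equal(one_sided_p(1.959964 * 2, 2), 0.025, tolerance = 1e-6)
  expect_gt(one_sided_p(-0.3, 1), 0.5)
  expect_equal(one_sided_p(1.959964, 1, df = Inf),
               pnorm(1.959964, lower.tail = FALSE))
  expect_error(one_sided_p(1, 0), "positive")
  expect_error(one_sided_p(1, -2), "positive")
})

test_that("fit_models returns one consistent row per method", {
  d <- small_design()
  sc <- scenario_spec(d, trend_spec("step", 0.1), "continuous",
                      theta = c(0.25, 0.25))
  dat <- simulate_trial(sc, seed = 9)
  res <- fit_models(dat, alpha = 0.025)
  expect_equal(nrow(res), length(ncc_methods()))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$reject, res$p_value <= 0.025)
  expect_true(all(res$se > 0))
})
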