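# Replicate simulation engine: operating characteristics for the test of
# H02 (type 1 error / power) and for the arm-2 effect estimate (bias, RMSE).

#' Per-replicate seeds derived from a base seed
#'
#' Draws one independent seed per replicate from the base seed, so that
#' replicate `r` is reproducible on its own and results do not depend on
#' execution order.
#'
#' @param base_seed integer base seed.
#' @param n_reps number of replicates.
#' @return integer vector of length `n_reps`.
#' @export
replicate_seeds <- function(base_seed, n_reps) {
  set.seed(base_seed)
  sample.int(2147483646L, n_reps)
}

#' Simulate operating characteristics for one scenario
#'
#' Runs `n_reps` replicate trials under a scenario and fits every requested
#' method to each replicate dataset (a paired design: all methods see the
#' same data, which removes between-method Monte-Carlo noise from their
#' comparison). Aggregates, per method, the rejection rate of the one-sided
#' test of `H02: theta2 <= 0` with its binomial Monte-Carlo standard error,
#' and the bias, RMSE and mean standard error of the arm-2 effect estimate.
#'
#' Replicates in which a fit does not converge are excluded from that
#' method's summaries and counted in `n_converged`.
#'
#' @param scenario a [scenario_spec()].
#' @param methods character vector of methods, see [ncc_methods()].
#' @param n_reps number of replicate trials.
#' @param base_seed integer; replicate `r` uses the seed
#'   `replicate_seeds(base_seed, n_reps)[r]`.
#' @param alpha one-sided significance level (default 0.025).
#' @param keep_replicates if `TRUE`, attach the per-replicate results as
#'   `attr(, "replicates")` (a long data.frame `rep`, `method`, `estimate`,
#'   `se`, `reject`, `converged`).
#' @return A `data.frame` of class `ncc_oc`, one row per method:
#'   `method`, `n_reps`, `n_converged`, `reject_rate`, `reject_mcse`,
#'   `bias`, `rmse`, `mean_se`, `theta2_true`, `base_seed`.
#' @examples
#' d <- trial_design(rbind(c(25, 25), c(25, 25), c(0, 50)))
#' sc <- scenario_spec(d, trend_spec("step", 0.15), "continuous",
#'                     theta = c(0.25, 0))
#' run_scenario(sc, c("ALLTC_step", "separate"), n_reps = 50, base_seed = 1)
#' @export
run_scenario <- function(scenario, methods = c("ALLTC_step", "ALLTCI_step",
                                               "pooled", "separate"),
                         n_reps, base_seed, alpha = 0.025,
                         keep_replicates = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  methods <- vapply(methods, match.arg, "", choices = ncc_methods(),
                    USE.NAMES = FALSE)
  check_methods_applicable(scenario, methods)
  theta2 <- unname(scenario$theta["2"])
  seeds <- replicate_seeds(base_seed, n_reps)

  M <- length(methods)
  est <- se <- matrix(NA_real_, n_reps, M, dimnames = list(NULL, methods))
  rej <- conv <- matrix(NA, n_reps, M, dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    dat <- simulate_trial(scenario, seed = seeds[r])
    for (m in seq_len(M)) {
      f <- fit_model(dat, methods[m], alpha = alpha,
                     endpoint = scenario$endpoint)
      conv[r, m] <- f$converged
      if (f$converged) {
        est[r, m] <- f$estimate
        se[r, m] <- f$se
        rej[r, m] <- f$reject
      }
    }
  }

  rows <- lapply(seq_len(M), function(m) {
    ok <- which(conv[, m])
    nc <- length(ok)
    pr <- mean(rej[ok, m])
    err <- est[ok, m] - theta2
    data.frame(
      method = methods[m],
      n_reps = n_reps,
      n_converged = nc,
      reject_rate = pr,
      reject_mcse = sqrt(pr * (1 - pr) / nc),
      bias = mean(err),
      rmse = sqrt(mean(err^2)),
      mean_se = mean(se[ok, m]),
      theta2_true = theta2,
      base_seed = base_seed
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ncc_oc", "data.frame")
  if (keep_replicates) {
    attr(out, "replicates") <- data.frame(
      rep = rep(seq_len(n_reps), M),
      method = rep(methods, each = n_reps),
      estimate = as.vector(est), se = as.vector(se),
      reject = as.vector(rej), converged = as.vector(conv)
    )
  }
  out
}

check_methods_applicable <- function(scenario, methods) {
  arms <- scenario$design$arms
  if (!2L %in% arms) stop("the design has no arm 2 to test")
  needs_arm1 <- c("ALLTC_step", "ALLTCI_step", "ALLTC_linear", "ALLTCI_linear")
  if (any(methods %in% needs_arm1) && !1L %in% arms) {
    stop("methods fitted on all arms require arm 1 in the design")
  }
  invisible(TRUE)
}

#' Build a grid of scenarios by crossing parameter values
#'
#' Expands vectors of scenario parameters into a named list of
#' [scenario_spec()] objects (the Cartesian product), for use with
#' [run_grid()]. Only the parameters being swept need to be vectors.
#'
#' @param design a [trial_design()].
#' @param endpoint `"continuous"` or `"binary"` (scalar).
#' @param pattern trend pattern(s).
#' @param lambda0,lambda1,lambda2 trend strengths per arm.
#' @param theta1,theta2 treatment effects (continuous endpoints).
#' @param OR1,OR2 odds ratios (binary endpoints).
#' @param eta0,sigma,p0 remaining scenario parameters (scalars).
#' @param Np,entry trend options passed to [trend_spec()].
#' @param randomisation passed to [scenario_spec()].
#' @return named list of scenarios; names encode the swept values.
#' @export
scenario_grid <- function(design, endpoint = "continuous",
                          pattern = "step",
                          lambda0 = 0, lambda1 = 0, lambda2 = 0,
                          theta1 = 0.25, theta2 = 0,
                          OR1 = 1.8, OR2 = 1,
                          eta0 = 0, sigma = 1, p0 = 0.7,
                          Np = "N1+N2/2", entry = "fixed",
                          randomisation = list(method = "block",
                                               block_sizes = c(4, 12))) {
  grid <- if (endpoint == "continuous") {
    expand.grid(pattern = pattern, lambda0 = lambda0, lambda1 = lambda1,
                lambda2 = lambda2, theta1 = theta1, theta2 = theta2,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(pattern = pattern, lambda0 = lambda0, lambda1 = lambda1,
                lambda2 = lambda2, OR1 = OR1, OR2 = OR2,
                stringsAsFactors = FALSE)
  }
  if (nrow(grid) == 0L) stop("empty scenario grid")
  scenarios <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tr <- trend_spec(g$pattern, lambda = c(g$lambda0, g$lambda1, g$lambda2),
                     Np = Np, entry = entry)
    if (endpoint == "continuous") {
      scenario_spec(design, tr, "continuous", eta0 = eta0,
                    theta = c(g$theta1, g$theta2), sigma = sigma,
                    randomisation = randomisation)
    } else {
      scenario_spec(design, tr, "binary", p0 = p0, OR = c(g$OR1, g$OR2),
                    randomisation = randomisation)
    }
  })
  names(scenarios) <- apply(grid, 1, function(g) {
    paste(paste0(names(grid), "=", trimws(unlist(g))), collapse = ",")
  })
  scenarios
}

#' Run a grid of scenarios
#'
#' Calls [run_scenario()] for every scenario in a list and stacks the
#' results into a long table, one row per scenario-method combination.
#' Each scenario gets its own base seed derived from `base_seed`, so the
#' whole grid is reproducible and scenario order is irrelevant.
#'
#' @param scenarios named list of [scenario_spec()] objects, e.g. from
#'   [scenario_grid()].
#' @inheritParams run_scenario
#' @param verbose if `TRUE`, report progress and per-scenario timing and
#'   non-convergence counts via [message()].
#' @return A `data.frame` with columns `scenario_id`, `endpoint`, `pattern`,
#'   `lambda0`, `lambda1`, `lambda2`, `hypothesis` (`"H0"` if the true
#'   arm-2 effect is null, else `"H1"`), `method`, `n_reps`, `n_converged`,
#'   `reject_rate`, `reject_mcse`, `bias`, `rmse`, `seed`.
#' @export
run_grid <- function(scenarios, methods = c("ALLTC_step", "ALLTCI_step",
                                            "pooled", "separate"),
                     n_reps, base_seed, alpha = 0.025, verbose = FALSE) {
  if (length(scenarios) == 0L) stop("empty scenario grid")
  if (is.null(names(scenarios))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  if (verbose) {
    message("Running ", length(scenarios), " scenario(s) x ",
            length(methods), " method(s), ", n_reps, " replicates each")
  }
  seeds <- replicate_seeds(base_seed, length(scenarios))
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    stopifnot(inherits(sc, "scenario_spec"))
    t0 <- proc.time()[["elapsed"]]
    oc <- run_scenario(sc, methods, n_reps = n_reps, base_seed = seeds[i],
                       alpha = alpha)
    if (verbose) {
      nonconv <- sum(oc$n_reps - oc$n_converged)
      message(sprintf("  %s: %.1fs, %d non-converged fit(s)",
                      names(scenarios)[i],
                      proc.time()[["elapsed"]] - t0, nonconv))
      if (sc$design$n_periods == 2L && length(sc$design$arms) >= 3L) {
        message(sprintf("    design rho = %.4f",
                        ncc_weights(sc$design$n)$rho))
      }
    }
    lam <- rep_len(sc$trend$lambda, 3L)
    data.frame(
      scenario_id = names(scenarios)[i],
      endpoint = sc$endpoint,
      pattern = sc$trend$pattern,
      lambda0 = lam[1], lambda1 = lam[2], lambda2 = lam[3],
      hypothesis = if (isTRUE(all.equal(unname(sc$theta["2"]), 0))) "H0" else "H1",
      method = oc$method,
      n_reps = oc$n_reps,
      n_converged = oc$n_converged,
      reject_rate = oc$reject_rate,
      reject_mcse = oc$reject_mcse,
      bias = oc$bias,
      rmse = oc$rmse,
      seed = oc$base_seed,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Trend strength in arm 1 that yields a target period-2 response
#'
#' Scenario sweeps are often described by the arm-1 response in period 2
#' (call it `X`) rather than by the trend strength directly. Under a step
#' trend, `X = g^{-1}(eta0 + theta1 + lambda1)`, so the required strength
#' on the model scale is `lambda1 = X - eta0 - theta1` for continuous
#' endpoints and `lambda1 = logit(X) - logit(p0) - log(OR1)` for binary
#' endpoints.
#'
#' @param X target arm-1 period-2 mean (continuous) or response rate
#'   (binary).
#' @param scenario a [scenario_spec()] supplying `eta0`/`p0` and the arm-1
#'   effect.
#' @return the trend strength `lambda1` on the model scale.
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' sc <- scenario_spec(d, trend_spec("step", 0.1), "continuous",
#'                     theta = c(0.25, 0))
#' lambda1_from_target(0.35, sc)  # 0.1: equal trends
#' @export
lambda1_from_target <- function(X, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (scenario$endpoint == "continuous") {
    X - scenario$eta0 - unname(scenario$theta["1"])
  } else {
    if (any(X <= 0 | X >= 1)) stop("target rates must lie strictly in (0, 1)")
    stats::qlogis(X) - scenario$eta0 - unname(scenario$theta["1"])
  }
}
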