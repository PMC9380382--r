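#' Specify a data-generating scenario
#'
#' Bundles everything needed to simulate one trial: the design, the time
#' trend, the endpoint type, the control response, the treatment effects and
#' the randomisation procedure. Outcomes are generated from
#' `g(E(Y_j)) = eta0 + theta_k + f(t_j)` where `g` is the identity link for
#' continuous endpoints (with iid normal residuals, SD `sigma`) and the
#' logit link for binary endpoints.
#'
#' @param design a [trial_design()].
#' @param trend a [trend_spec()]; defaults to no trend.
#' @param endpoint `"continuous"` or `"binary"`.
#' @param eta0 control response in period 1, on the model scale. For binary
#'   endpoints supply `p0` instead (the control response probability);
#'   internally `eta0 = qlogis(p0)`.
#' @param theta treatment effects for arms `1, 2, ...` on the model scale:
#'   mean differences (continuous) or log odds ratios (binary). For binary
#'   endpoints supply `OR` instead.
#' @param sigma residual SD (continuous endpoints only), default 1.
#' @param p0,OR binary-endpoint parameterisation: control response rate and
#'   odds ratios per treatment arm (`OR = 1` means no effect).
#' @param randomisation list with elements `method` (`"block"` or
#'   `"simple"`), `block_sizes` (per period) and, for simple randomisation,
#'   `conditional`; see [allocate()]. Default: block randomisation with
#'   block sizes 4 and 12 (the 1:1 and 2:1:1 allocation blocks of the
#'   reference design), recycled over periods.
#'
#' @return An object of class `scenario_spec`. `theta` is always stored on
#'   the model scale; `scenario$theta[2]` is the true effect of the newly
#'   added arm 2 that the simulation engine measures bias against.
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' scenario_spec(d, trend_spec("step", 0.15), "continuous",
#'               theta = c(0.25, 0.25))
#' scenario_spec(d, trend_spec("step", 0.25), "binary",
#'               p0 = 0.7, OR = c(1.8, 1.8))
#' @export
scenario_spec <- function(design,
                          trend = trend_spec("step", 0),
                          endpoint = c("continuous", "binary"),
                          eta0 = 0, theta = NULL, sigma = 1,
                          p0 = NULL, OR = NULL,
                          randomisation = list(method = "block",
                                               block_sizes = c(4, 12))) {
  stopifnot(inherits(design, "trial_design"), inherits(trend, "trend_spec"))
  endpoint <- match.arg(endpoint)
  n_trt <- length(design$arms) - 1L

  if (endpoint == "binary") {
    if (is.null(p0) || is.null(OR)) {
      stop("binary scenarios are parameterised by `p0` and `OR`")
    }
    if (p0 <= 0 || p0 >= 1) stop("`p0` must lie strictly between 0 and 1")
    if (any(OR <= 0)) stop("odds ratios must be positive")
    OR <- rep_len(OR, n_trt)
    eta0 <- stats::qlogis(p0)
    theta <- log(OR)
    sigma <- NA_real_
  } else {
    if (is.null(theta)) stop("continuous scenarios need `theta` (mean differences)")
    if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be positive")
    theta <- rep_len(theta, n_trt)
    p0 <- NULL; OR <- NULL
  }
  names(theta) <- as.character(seq_len(n_trt))

  if (is.null(randomisation$method)) randomisation$method <- "block"
  structure(list(design = design, trend = trend, endpoint = endpoint,
                 eta0 = eta0, theta = theta, sigma = sigma,
                 p0 = p0, OR = OR, randomisation = randomisation),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario:", x$endpoint, "endpoint, N =", x$design$N, "\n")
  if (x$endpoint == "binary") {
    cat("  p0 =", x$p0, "| OR =", paste(round(x$OR, 3), collapse = ", "), "\n")
  } else {
    cat("  eta0 =", x$eta0, "| theta =", paste(x$theta, collapse = ", "),
        "| sigma =", x$sigma, "\n")
  }
  print(x$trend)
  invisible(x)
}

# model-scale linear predictor for given arms and entry positions
scenario_linpred <- function(scenario, arm, t_trend) {
  theta_term <- c(0, unname(scenario$theta))[arm + 1L]
  N1 <- scenario$design$cutpoints[1L]
  scenario$eta0 + theta_term +
    trend_value(scenario$trend, arm, t_trend, scenario$design$N, N1)
}

#' Simulate one trial dataset
#'
#' Allocates patients to arms according to the scenario's randomisation
#' settings and draws outcomes from the scenario's data-generating model.
#'
#' @param scenario a [scenario_spec()].
#' @param seed optional integer seed for reproducibility (sets the RNG
#'   before allocation and outcome draws).
#' @return A `data.frame` with one row per patient and columns `j` (enrolment
#'   index), `t` (entry time; equals `j` under fixed entry), `arm`, `period`
#'   and `y`. The endpoint type is attached as `attr(, "endpoint")` and the
#'   seed as `attr(, "seed")`.
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' sc <- scenario_spec(d, trend_spec("step", 0.15), "continuous",
#'                     theta = c(0.25, 0))
#' head(simulate_trial(sc, seed = 1))
#' @export
simulate_trial <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  design <- scenario$design
  r <- scenario$randomisation
  alloc <- allocate(design, method = r$method, block_sizes = r$block_sizes,
                    conditional = if (is.null(r$conditional)) TRUE else r$conditional)
  N <- design$N
  j <- seq_len(N)
  t <- if (scenario$trend$entry == "random") sort(stats::runif(N, 1, N)) else as.numeric(j)
  # the step pattern keeps the enrolment-index period indicator even under
  # random entry times; smooth patterns are evaluated at the entry time
  t_trend <- if (scenario$trend$pattern == "step") as.numeric(j) else t
  mu <- scenario_linpred(scenario, alloc$arm, t_trend)
  y <- if (scenario$endpoint == "continuous") {
    stats::rnorm(N, mean = mu, sd = scenario$sigma)
  } else {
    stats::rbinom(N, 1L, stats::plogis(mu))
  }
  out <- data.frame(j = j, t = t, arm = alloc$arm, period = alloc$period, y = y)
  attr(out, "endpoint") <- scenario$endpoint
  attr(out, "seed") <- seed
  out
}

#' Expected outcome per arm-by-period cell
#'
#' The expected response (mean for continuous, response rate for binary
#' endpoints) of each design cell. Under a step trend the mean function is
#' constant within each period and the cell values are exact; under the
#' smooth patterns the cell value is the average of the mean function over
#' the period's enrolment indices.
#'
#' @param scenario a [scenario_spec()].
#' @return numeric matrix, arms by periods; `NA` for cells the design does
#'   not recruit (e.g. arm 2 in period 1).
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' sc <- scenario_spec(d, trend_spec("step", 0.25), "binary",
#'                     p0 = 0.7, OR = c(1.8, 1.8))
#' round(expected_cell_means(sc), 2)  # control period 2 = 0.75, arm 1 period 1 = 0.81
#' @export
expected_cell_means <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  design <- scenario$design
  linkinv <- if (scenario$endpoint == "binary") stats::plogis else identity
  periods <- design_periods(design)
  j <- seq_len(design$N)
  out <- matrix(NA_real_, nrow = length(design$arms), ncol = design$n_periods,
                dimnames = dimnames(design$n))
  for (k in design$arms) {
    mu_k <- linkinv(scenario_linpred(scenario, rep.int(k, design$N), j))
    for (s in seq_len(design$n_periods)) {
      if (design$n[k + 1L, s] > 0L) {
        out[k + 1L, s] <- mean(mu_k[periods == s])
      }
    }
  }
  out
}

#' Observed cell means and counts of a trial dataset
#'
#' @param data a trial dataset as produced by [simulate_trial()] or read by
#'   [read_trial_data()] (columns `arm`, `period`, `y`).
#' @param n_arms,n_periods optional dimensions; defaults to the arms/periods
#'   present in the data.
#' @return A list with `means` and `counts`, both arms-by-periods matrices
#'   (`NA`/0 for empty cells), suitable for the closed-form estimators
#'   [theta2_weighted()] and [control_estimate_period2()].
#' @export
cell_stats <- function(data, n_arms = NULL, n_periods = NULL) {
  if (!all(c("arm", "period", "y") %in% names(data))) {
    stop("`data` must have columns arm, period, y")
  }
  K <- if (is.null(n_arms)) max(data$arm) + 1L else n_arms
  S <- if (is.null(n_periods)) max(data$period) else n_periods
  arm_f <- factor(data$arm, levels = 0:(K - 1L))
  per_f <- factor(data$period, levels = seq_len(S))
  counts <- table(arm_f, per_f)
  means <- tapply(data$y, list(arm_f, per_f), mean)
  counts <- matrix(as.integer(counts), nrow = K,
                   dimnames = list(paste0("arm", 0:(K - 1L)),
                                   paste0("period", seq_len(S))))
  means <- matrix(as.numeric(means), nrow = K, dimnames = dimnames(counts))
  list(means = means, counts = counts)
}
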