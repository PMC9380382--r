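# Closed-form weighted-means representation of the step-adjusted estimator.
#
# In the two-period design the least-squares estimate of the arm-2 effect
# from the model
#     E(Y_j) = eta0 + theta1 I(k_j = 1) + theta2 I(k_j = 2) + nu I(j > N1)
# can be written as a weighted sum of the six arm-by-period cell means,
#     theta2_hat = sum_{k,s} w_{k,s} ybar_{k,s},
# with a single free weight rho attached to the between-period arm-1
# contrast. rho is also the fraction by which the model-based period-2
# control estimate reduces the variance of the plain concurrent-control
# mean: 1 - Var(y0,2~)/Var(ybar_{0,2}) = rho.

cells_from <- function(n) {
  # accept a 3x2 (or larger, with only the 3x2 core used) count matrix and
  # return the four informative control/arm-1 cells
  if (is.matrix(n)) {
    if (nrow(n) < 3L || ncol(n) < 2L) {
      stop("count matrix must be at least 3 arms by 2 periods")
    }
    list(n01 = n[1, 1], n11 = n[2, 1], n02 = n[1, 2], n12 = n[2, 2],
         n21 = n[3, 1], n22 = n[3, 2])
  } else {
    stop("expected an arms-by-periods count matrix")
  }
}

check_rho_counts <- function(n01, n11, n02, n12) {
  counts <- c(n01 = n01, n11 = n11, n02 = n02, n12 = n12)
  if (anyNA(counts) || any(counts < 1)) {
    stop("all of n01, n11, n02, n12 must be >= 1 (the weighted-means ",
         "representation is undefined for empty cells)")
  }
  invisible(counts)
}

#' Weight of the non-concurrent controls in the step-adjusted estimator
#'
#' `ncc_rho()` returns the scalar weight `rho` that the step-function model
#' fitted on all arms places on the between-period contrast of arm 1,
#' i.e. on the non-concurrent-control information:
#' \deqn{\varrho = \frac{1/n_{0,2}}{1/n_{0,1} + 1/n_{1,1} + 1/n_{0,2} + 1/n_{1,2}}.}
#' The same quantity is the relative variance reduction of the model-based
#' period-2 control estimate compared to the concurrent-control mean, which
#' is what [variance_reduction()] reports.
#'
#' @param n01,n11,n02,n12 cell counts: control and arm 1 in period 1
#'   (`n01`, `n11`) and in period 2 (`n02`, `n12`). All must be `>= 1`.
#'   The arm-2 counts do not enter: `rho` does not depend on them.
#' @return `rho`, a number in `(0, 1)`.
#'
#' @details Limits and monotonicity: `rho` increases in `n01`, `n11` and
#'   `n12` and decreases in `n02`; `rho -> 0` as `n02 -> Inf` (with many
#'   concurrent controls the non-concurrent data add nothing) and
#'   `rho -> 1` as `n01, n11, n12 -> Inf` with `n02` fixed. Under equal
#'   control/arm-1 allocation per period (`n01 = n11`, `n02 = n12`) it
#'   simplifies to `(1/2) * n01 / (n01 + n02)` — half the proportion of
#'   non-concurrent controls among all controls, hence always below 1/2.
#'   With 125 patients per cell, `rho = 0.25`.
#'
#' @examples
#' ncc_rho(125, 125, 125, 125)  # 0.25
#' ncc_rho(100, 50, 200, 25)    # 1/15
#' @seealso [ncc_weights()], [theta2_weighted()], [variance_reduction()]
#' @export
ncc_rho <- function(n01, n11, n02, n12) {
  check_rho_counts(n01, n11, n02, n12)
  (1 / n02) / (1 / n01 + 1 / n11 + 1 / n02 + 1 / n12)
}

#' Relative variance reduction from using non-concurrent controls
#'
#' The fraction by which the model-based estimate of the period-2 control
#' response (see [control_estimate_period2()]) reduces the variance of the
#' plain period-2 control mean: `1 - Var(y0,2~)/Var(ybar_{0,2})`. This
#' equals the non-concurrent-control weight [ncc_rho()] exactly: writing
#' `y0,2~ = (1 - rho) ybar_{0,2} + rho [ybar_{0,1} + (ybar_{1,2} - ybar_{1,1})]`
#' with independent cell means of variance `sigma^2 / n_{k,s}` gives
#' `Var(y0,2~) = (1 - rho) * sigma^2 / n_{0,2}`.
#'
#' @inheritParams ncc_rho
#' @return the variance-reduction fraction, in `(0, 1)`.
#' @examples
#' variance_reduction(125, 125, 125, 125)  # 0.25: 25% lower variance
#' @export
variance_reduction <- function(n01, n11, n02, n12) {
  ncc_rho(n01, n11, n02, n12)
}

#' Weight matrix of the step-adjusted estimator
#'
#' Expands the arm-2 effect estimate of the step-function model on all arms
#' into its weighted-means form `theta2_hat = sum w_{k,s} ybar_{k,s}`.
#' The weights are determined by the single scalar `rho = ` [ncc_rho()]:
#' `w_{2,2} = 1`, `w_{0,2} = -(1 - rho)`, `w_{0,1} = -rho`, `w_{1,1} = rho`,
#' `w_{1,2} = -rho`, `w_{2,1} = 0`; they sum to zero.
#'
#' @param n arms-by-periods count matrix (3 arms, 2 periods; arm 2 must
#'   have no period-1 patients).
#' @return An object of class `ncc_weights`: list with the 3-by-2 weight
#'   matrix `w`, the scalar `rho` and the counts `n`.
#' @examples
#' d <- rbind(c(125, 125), c(125, 125), c(0, 250))
#' ncc_weights(d)$w
#' @export
ncc_weights <- function(n) {
  cells <- cells_from(n)
  if (cells$n21 != 0) {
    stop("the closed-form weights assume arm 2 enters in period 2 (n21 = 0)")
  }
  rho <- ncc_rho(cells$n01, cells$n11, cells$n02, cells$n12)
  w <- matrix(c(-rho, rho, 0,
                -(1 - rho), -rho, 1),
              nrow = 3L,
              dimnames = list(c("arm0", "arm1", "arm2"),
                              c("period1", "period2")))
  structure(list(w = w, rho = rho, n = n), class = "ncc_weights")
}

#' @export
print.ncc_weights <- function(x, ...) {
  cat("Weighted-means representation, rho =", format(x$rho), "\n")
  print(x$w)
  invisible(x)
}

#' Closed-form treatment-effect estimate for the newly added arm
#'
#' Computes the step-function-model estimate of the arm-2 effect directly
#' from cell means and counts:
#' \deqn{\tilde\theta_2 = (\bar y_{2,2} - \bar y_{0,2}) +
#'   \varrho\,[(\bar y_{1,1} - \bar y_{0,1}) - (\bar y_{1,2} - \bar y_{0,2})].}
#' It is numerically identical to the least-squares estimate of
#' [fit_model()] with method `"ALLTC_step"` on the same data; the second
#' term is the correction the model applies using the non-concurrent
#' controls via arm 1's between-period shift.
#'
#' @param means arms-by-periods matrix of cell means (`ybar_{k,s}`), e.g.
#'   from [cell_stats()].
#' @param n arms-by-periods matrix of cell counts.
#' @return the estimate `theta2~`.
#' @examples
#' n <- rbind(c(125, 125), c(125, 125), c(0, 250))
#' m <- rbind(c(0, 0.1), c(0.25, 0.35), c(NA, 0.35))
#' theta2_weighted(m, n)  # 0.25
#' @export
theta2_weighted <- function(means, n) {
  wts <- ncc_weights(n)
  m <- cells_means_from(means)
  (m$y22 - m$y02) + wts$rho * ((m$y11 - m$y01) - (m$y12 - m$y02))
}

cells_means_from <- function(means) {
  if (!is.matrix(means) || nrow(means) < 3L || ncol(means) < 2L) {
    stop("expected an arms-by-periods matrix of cell means")
  }
  m <- list(y01 = means[1, 1], y11 = means[2, 1],
            y02 = means[1, 2], y12 = means[2, 2], y22 = means[3, 2])
  if (anyNA(unlist(m))) stop("a required cell mean is missing (NA)")
  m
}

#' Model-based estimate of the period-2 control response
#'
#' The step-function model estimates the control response in period 2 by
#' shrinking the concurrent-control mean towards the period-1 control mean
#' shifted by arm 1's between-period change:
#' \deqn{\tilde y_{0,2} = (1-\varrho)\,\bar y_{0,2} +
#'   \varrho\,[\bar y_{0,1} + (\bar y_{1,2} - \bar y_{1,1})].}
#' The identity `theta2~ = ybar_{2,2} - y0,2~` links it to
#' [theta2_weighted()], and its variance is `(1 - rho)` times that of
#' `ybar_{0,2}` (see [variance_reduction()]).
#'
#' @inheritParams theta2_weighted
#' @return the model-based control estimate `y0,2~`.
#' @export
control_estimate_period2 <- function(means, n) {
  wts <- ncc_weights(n)
  m <- cells_means_from(means)
  (1 - wts$rho) * m$y02 + wts$rho * (m$y01 + (m$y12 - m$y11))
}

#' Analytic power of the pooled two-sample test
#'
#' Power calculators used to calibrate scenario effect sizes: the exact
#' noncentral-t power of the one-sided two-sample pooled-variance t-test
#' (continuous endpoints), and the normal-approximation power of the
#' two-sample z-test for proportions (binary endpoints).
#'
#' @param endpoint `"continuous"` or `"binary"`.
#' @param n per-group sample size: a scalar (both groups equal) or a
#'   vector `c(n0, n1)`.
#' @param delta mean difference (continuous).
#' @param sigma common residual SD (continuous), default 1.
#' @param p0 control response rate (binary).
#' @param OR odds ratio of the treatment group versus control (binary).
#' @param alpha one-sided significance level, default 0.025.
#' @param variance for binary endpoints, the variance used in the critical
#'   region: `"unpooled"` (default) evaluates both the critical value and
#'   the distribution of the test statistic under the alternative-variance
#'   normal approximation; `"pooled"` uses the pooled-proportion variance
#'   for the critical value. The two differ by well under a percentage
#'   point at the designs considered here.
#' @return the power, a number in `(0, 1)`; equals `alpha` when the effect
#'   is null.
#' @examples
#' power_pooled("continuous", n = 250, delta = 0.25)          # about 0.80
#' power_pooled("binary", n = 250, p0 = 0.7, OR = 1.8)        # about 0.80
#' @export
power_pooled <- function(endpoint = c("continuous", "binary"), n,
                         delta = NULL, sigma = 1, p0 = NULL, OR = NULL,
                         alpha = 0.025, variance = c("unpooled", "pooled")) {
  endpoint <- match.arg(endpoint)
  variance <- match.arg(variance)
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)")
  n <- rep_len(n, 2L)
  if (any(n < 2)) stop("per-group sizes must be at least 2")
  if (endpoint == "continuous") {
    if (is.null(delta)) stop("continuous power needs `delta`")
    if (sigma <= 0) stop("`sigma` must be positive")
    df <- sum(n) - 2
    ncp <- delta / (sigma * sqrt(1 / n[1] + 1 / n[2]))
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    if (is.null(p0) || is.null(OR)) stop("binary power needs `p0` and `OR`")
    if (p0 <= 0 || p0 >= 1) stop("`p0` must lie strictly between 0 and 1")
    if (OR <= 0) stop("`OR` must be positive")
    p1 <- stats::plogis(stats::qlogis(p0) + log(OR))
    d <- p1 - p0
    se_alt <- sqrt(p0 * (1 - p0) / n[1] + p1 * (1 - p1) / n[2])
    z <- stats::qnorm(1 - alpha)
    if (variance == "unpooled") {
      stats::pnorm(d / se_alt - z)
    } else {
      pbar <- (n[1] * p0 + n[2] * p1) / sum(n)
      se0 <- sqrt(pbar * (1 - pbar) * (1 / n[1] + 1 / n[2]))
      stats::pnorm((d - z * se0) / se_alt)
    }
  }
}
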