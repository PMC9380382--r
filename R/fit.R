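#' Analysis methods for the newly added arm
#'
#' `ncc_methods()` lists the analysis methods [fit_model()] understands.
#' All of them estimate the effect of arm 2 versus control and test the
#' one-sided null `H02: theta2 <= 0` (larger outcomes are better):
#' \describe{
#'   \item{ALLTC_step}{regression on all arms with a period factor
#'     (step-function time adjustment): treatment indicators plus
#'     `I(j > N1)`. The reference method; it is the only one through which
#'     non-concurrent controls contribute to the effect estimate.}
#'   \item{ALLTCI_step}{as `ALLTC_step` plus an arm-1-by-period interaction,
#'     allowing arm 1 its own time trend. The arm-2 estimate then reduces to
#'     the concurrent comparison `ybar_{2,2} - ybar_{0,2}`.}
#'   \item{TC_step}{step-adjusted regression on control and arm 2 only.}
#'   \item{ALLTC_linear, ALLTCI_linear, TC_linear}{the same three models
#'     with the period factor replaced by a linear term in the enrolment
#'     index `j` (patients are assumed to arrive at a uniform pace, so the
#'     index is proportional to calendar time).}
#'   \item{pooled}{arm 2 versus all controls (concurrent and
#'     non-concurrent pooled), no time adjustment.}
#'   \item{separate}{arm 2 versus concurrent controls only.}
#' }
#'
#' @return character vector of method names.
#' @export
ncc_methods <- function() {
  c("ALLTC_step", "ALLTCI_step", "TC_step",
    "ALLTC_linear", "ALLTCI_linear", "TC_linear",
    "pooled", "separate")
}

# subset + design matrix for one method; returns list(X, y, n)
model_frame <- function(data, method) {
  if (!all(c("j", "arm", "period", "y") %in% names(data))) {
    stop("`data` must have columns j, arm, period, y")
  }
  all_arms <- method %in% c("ALLTC_step", "ALLTCI_step",
                            "ALLTC_linear", "ALLTCI_linear")
  if (!any(data$arm == 2)) stop("method ", method, " requires arm 2 in the data")
  if (all_arms && !any(data$arm == 1)) {
    stop("method ", method, " requires data from all arms incl. arm 1")
  }
  d <- if (all_arms) data else data[data$arm %in% c(0L, 2L), , drop = FALSE]
  if (method == "separate") {
    concurrent <- unique(d$period[d$arm == 2])
    d <- d[d$period %in% concurrent, , drop = FALSE]
  }
  if (!any(d$arm == 0)) stop("method ", method, " requires control data")

  n <- nrow(d)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  for (k in sort(unique(d$arm[d$arm > 0]))) {
    X <- cbind(X, as.numeric(d$arm == k))
    colnames(X)[ncol(X)] <- paste0("arm", k)
  }
  step <- method %in% c("ALLTC_step", "ALLTCI_step", "TC_step")
  linear <- method %in% c("ALLTC_linear", "ALLTCI_linear", "TC_linear")
  if (step) {
    for (s in sort(unique(d$period))[-1]) {
      X <- cbind(X, as.numeric(d$period == s))
      colnames(X)[ncol(X)] <- paste0("period", s)
    }
  } else if (linear) {
    X <- cbind(X, j = as.numeric(d$j))
  }
  if (method == "ALLTCI_step") {
    for (s in sort(unique(d$period))[-1]) {
      col <- as.numeric(d$arm == 1 & d$period == s)
      if (any(col > 0)) {
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0("arm1:period", s)
      }
    }
  } else if (method == "ALLTCI_linear") {
    X <- cbind(X, "arm1:j" = as.numeric(d$j) * as.numeric(d$arm == 1))
  }
  list(X = X, y = d$y, n = n)
}

#' Fit an analysis method and test the effect of the newly added arm
#'
#' Fits one of the analysis methods of [ncc_methods()] to a trial dataset
#' and returns the arm-2 effect estimate together with a one-sided test of
#' `H02: theta2 <= 0`.
#'
#' Continuous endpoints are analysed by ordinary least squares with the
#' classical covariance; the test is a t-test on the residual degrees of
#' freedom. The `pooled` and `separate` methods are then exactly the
#' equal-variance two-sample t-test (set `var_equal = FALSE` for Welch).
#' Binary endpoints are analysed by maximum-likelihood logistic regression
#' (IRLS via [stats::glm.fit()], score tolerance `1e-8`, at most 50
#' iterations) with a Wald z-test. Non-convergence or separation is
#' reported through the `converged` flag and `NA` estimates, never as a
#' silent number.
#'
#' @param data a trial dataset (columns `j`, `arm`, `period`, `y`); the
#'   endpoint is read from `attr(data, "endpoint")` unless given.
#' @param method one of [ncc_methods()].
#' @param alpha one-sided significance level (default 0.025).
#' @param endpoint `"continuous"` or `"binary"`.
#' @param var_equal continuous `pooled`/`separate` only: pooled-SD t-test
#'   (`TRUE`, default) or Welch (`FALSE`).
#' @return An object of class `ncc_fit`: list with `method`, `endpoint`,
#'   `estimate` (the arm-2 effect on the model scale), `se`, `df`
#'   (`Inf` for Wald z), `statistic`, `p_value` (one-sided, upper tail),
#'   `reject`, `alpha`, `coefficients` (full vector), `sigma` (residual SD,
#'   continuous), `converged`, `iter` and `n_used`.
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' sc <- scenario_spec(d, trend_spec("step", 0.15), "continuous",
#'                     theta = c(0.25, 0.25))
#' dat <- simulate_trial(sc, seed = 7)
#' fit_model(dat, "ALLTC_step")
#' @export
fit_model <- function(data, method, alpha = 0.025,
                      endpoint = attr(data, "endpoint"), var_equal = TRUE) {
  method <- match.arg(method, ncc_methods())
  if (is.null(endpoint)) {
    stop("`endpoint` not given and not attached to the dataset")
  }
  endpoint <- match.arg(endpoint, c("continuous", "binary"))
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5)")

  if (endpoint == "continuous" && !var_equal &&
      method %in% c("pooled", "separate")) {
    return(fit_welch(data, method, alpha))
  }

  mf <- model_frame(data, method)
  X <- mf$X
  y <- mf$y

  if (endpoint == "continuous") {
    fit <- stats::lm.fit(X, y)
    p <- fit$rank
    df <- mf$n - p
    if (df < 1) stop("zero residual degrees of freedom")
    coefs <- fit$coefficients
    if (anyNA(coefs)) stop("rank-deficient design matrix for method ", method)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / df
    cov <- sigma2 * unpivoted_xtx_inverse(fit$qr)
    se <- sqrt(diag(cov))
    est <- coefs[["arm2"]]
    se2 <- se[["arm2"]]
    # an exactly saturated fit (rss == 0) still has a valid estimate but
    # leaves nothing to test
    pval <- if (se2 > 0) one_sided_p(est, se2, df) else NA_real_
    return(new_ncc_fit(method, endpoint, est, se2, df, pval, alpha,
                       coefs, sigma = sqrt(sigma2), converged = TRUE,
                       iter = NA_integer_, n_used = mf$n, vcov = cov))
  }

  # binary: IRLS logistic fit with Wald inference
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  coefs <- fit$coefficients
  ok <- fit$converged && !fit$boundary && !anyNA(coefs)
  se2 <- NA_real_
  if (ok) {
    cov <- unpivoted_xtx_inverse(fit$qr)
    se <- sqrt(diag(cov))
    se2 <- se[["arm2"]]
    # absurd Wald SEs on the log-odds scale signal (quasi-)separation
    if (!is.finite(se2) || se2 > 100) ok <- FALSE
  }
  if (!ok) {
    return(new_ncc_fit(method, endpoint, NA_real_, NA_real_, Inf, NA_real_,
                       alpha, coefs, sigma = NA_real_, converged = FALSE,
                       iter = fit$iter, n_used = mf$n))
  }
  est <- coefs[["arm2"]]
  pval <- one_sided_p(est, se2, Inf)
  new_ncc_fit(method, endpoint, est, se2, Inf, pval, alpha, coefs,
              sigma = NA_real_, converged = TRUE, iter = fit$iter,
              n_used = mf$n, vcov = cov)
}

# (X'X)^{-1} (or (X'WX)^{-1} for IRLS) from a possibly pivoted QR
unpivoted_xtx_inverse <- function(qr_obj) {
  p <- qr_obj$rank
  R <- qr_obj$qr[seq_len(p), seq_len(p), drop = FALSE]
  R[lower.tri(R)] <- 0
  inv <- chol2inv(R)           # in pivoted column order
  piv <- qr_obj$pivot[seq_len(p)]
  out <- matrix(NA_real_, p, p)
  out[piv, piv] <- inv         # back to the original column order
  nm <- character(p)
  nm[piv] <- colnames(qr_obj$qr)[seq_len(p)]
  dimnames(out) <- list(nm, nm)
  out
}

fit_welch <- function(data, method, alpha) {
  mf <- model_frame(data, method)
  y2 <- mf$y[mf$X[, "arm2"] == 1]
  y0 <- mf$y[mf$X[, "arm2"] == 0]
  tt <- stats::t.test(y2, y0, alternative = "greater", var.equal = FALSE)
  est <- unname(diff(rev(tt$estimate)))
  se <- tt$stderr
  coefs <- c("(Intercept)" = mean(y0), arm2 = est)
  new_ncc_fit(method, "continuous", est, se, unname(tt$parameter),
              unname(tt$p.value), alpha, coefs,
              sigma = NA_real_, converged = TRUE, iter = NA_integer_,
              n_used = mf$n)
}

new_ncc_fit <- function(method, endpoint, estimate, se, df, p_value, alpha,
                        coefficients, sigma, converged, iter, n_used,
                        vcov = NULL) {
  structure(list(
    method = method, endpoint = endpoint,
    estimate = unname(estimate), se = unname(se), df = df,
    statistic = unname(estimate / se), p_value = unname(p_value),
    reject = if (is.na(p_value)) NA else p_value <= alpha,
    alpha = alpha, coefficients = coefficients, sigma = sigma,
    vcov = vcov, converged = converged, iter = iter, n_used = n_used
  ), class = "ncc_fit")
}

#' @export
print.ncc_fit <- function(x, digits = 4, ...) {
  cat(x$method, " (", x$endpoint, "), n = ", x$n_used, "\n", sep = "")
  if (!x$converged) {
    cat("  fit did not converge (", x$iter, " iterations); no estimate\n", sep = "")
    return(invisible(x))
  }
  cat("  theta2 = ", format(x$estimate, digits = digits),
      " (SE ", format(x$se, digits = digits), ")",
      ", one-sided p = ", format(x$p_value, digits = digits),
      if (isTRUE(x$reject)) "  [reject H02]" else "", "\n", sep = "")
  invisible(x)
}

#' Fit several methods to the same dataset
#'
#' @inheritParams fit_model
#' @param methods character vector of methods, default all of
#'   [ncc_methods()].
#' @return A `data.frame` with one row per method: `method`, `estimate`,
#'   `se`, `df`, `p_value`, `reject`, `converged`, `n_used`.
#' @export
fit_models <- function(data, methods = ncc_methods(), alpha = 0.025,
                       endpoint = attr(data, "endpoint"), var_equal = TRUE) {
  rows <- lapply(methods, function(m) {
    f <- fit_model(data, m, alpha = alpha, endpoint = endpoint,
                   var_equal = var_equal)
    data.frame(method = f$method, estimate = f$estimate, se = f$se,
               df = f$df, p_value = f$p_value, reject = f$reject,
               converged = f$converged, n_used = f$n_used)
  })
  do.call(rbind, rows)
}

#' One-sided upper-tail p-value
#'
#' p-value for the one-sided null `H0: theta <= 0` against `theta > 0`,
#' based on `estimate / se` referred to a t distribution with `df` degrees
#' of freedom (`df = Inf` gives the standard normal, as used for Wald z
#' tests).
#'
#' @param estimate effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @param df degrees of freedom; `Inf` (default) for the normal reference.
#' @return p-value(s) in `[0, 1]`; 0.5 at `estimate = 0`, above 0.5 for
#'   negative estimates.
#' @export
one_sided_p <- function(estimate, se, df = Inf) {
  if (any(!is.finite(se)) || any(se <= 0)) stop("`se` must be positive")
  stats::pt(estimate / se, df = df, lower.tail = FALSE)
}
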