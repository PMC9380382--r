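#' Specify a time trend
#'
#' Describes how the outcome level drifts with patient enrolment, on the
#' scale of the analysis model (outcome units for continuous endpoints,
#' log-odds for binary endpoints). Trends may differ between arms: the
#' strength `lambda` can be a single number (equal trends) or one value per
#' arm.
#'
#' Three patterns are available, written as functions of the enrolment
#' index `j` (with `N` the overall and `N1` the period-1 sample size):
#' \describe{
#'   \item{linear}{`lambda * (j - 1) / (N - 1)`: drift from 0 to `lambda`.}
#'   \item{step}{`lambda * I(j > N1)`: a jump of `lambda` at the period
#'     boundary; the adjustment model with a period factor is then exactly
#'     correct.}
#'   \item{inverse_u}{`lambda * (j - 1) / (N - 1) * (I(j <= Np) - I(j > Np))`:
#'     rises like the linear trend up to the turning point `Np`, then the
#'     whole term flips sign. A negative `lambda` gives the corresponding
#'     U shape.}
#' }
#'
#' @param pattern `"linear"`, `"step"` or `"inverse_u"`.
#' @param lambda trend strength per arm: a scalar (shared by all arms) or a
#'   vector with one entry per arm in arm order `0, 1, 2, ...`.
#' @param Np turning point of the inverse-U trend: an integer patient index,
#'   or one of the strings `"N1/2"`, `"N1"`, `"N1+N2/2"` resolved against
#'   the design at evaluation time. Defaults to `"N1+N2/2"`.
#' @param entry `"fixed"` (patient `j` enters at time `t = j`, the default)
#'   or `"random"` (entry times are `N` sorted uniform draws on `[1, N]`,
#'   substituted for `j` in the linear and inverse-U patterns; the step
#'   pattern keeps the enrolment-index period indicator).
#' @param inverse_u_continuous if `TRUE`, replace the sign-flip form by a
#'   continuous "tent" `lambda * ((Np - 1) - |j - Np|) / (N - 1)` that rises
#'   to the same peak and descends at the same rate. Off by default: the
#'   sign-flip form, including its jump at `Np`, is the reference shape;
#'   the tent is a sensitivity variant.
#'
#' @return An object of class `trend_spec`.
#' @examples
#' trend_spec("step", lambda = 0.15)
#' trend_spec("inverse_u", lambda = c(0.1, 0.2, 0.1), Np = "N1")
#' @export
trend_spec <- function(pattern = c("linear", "step", "inverse_u"),
                       lambda = 0,
                       Np = "N1+N2/2",
                       entry = c("fixed", "random"),
                       inverse_u_continuous = FALSE) {
  pattern <- match.arg(pattern)
  entry <- match.arg(entry)
  if (!is.numeric(lambda) || anyNA(lambda)) {
    stop("`lambda` must be numeric (scalar or one value per arm)")
  }
  if (is.character(Np)) {
    if (!Np %in% c("N1/2", "N1", "N1+N2/2")) {
      stop('symbolic `Np` must be one of "N1/2", "N1", "N1+N2/2"')
    }
  } else if (!(is.numeric(Np) && length(Np) == 1L && Np == round(Np))) {
    stop("`Np` must be an integer or a symbolic turning point")
  }
  structure(list(pattern = pattern, lambda = lambda, Np = Np, entry = entry,
                 inverse_u_continuous = isTRUE(inverse_u_continuous)),
            class = "trend_spec")
}

#' @export
print.trend_spec <- function(x, ...) {
  cat("Time trend:", x$pattern,
      "| lambda =", paste(x$lambda, collapse = ", "),
      if (x$pattern == "inverse_u") paste("| Np =", x$Np) else "",
      "| entry:", x$entry, "\n")
  invisible(x)
}

trend_lambda <- function(spec, arm) {
  if (length(spec$lambda) == 1L) return(rep_len(spec$lambda, length(arm)))
  if (any(arm + 1L > length(spec$lambda))) {
    stop("`lambda` has fewer entries than the design has arms")
  }
  spec$lambda[arm + 1L]
}

resolve_np <- function(Np, N, N1) {
  if (is.character(Np)) {
    Np <- switch(Np,
                 "N1/2"    = N1 / 2,
                 "N1"      = N1,
                 "N1+N2/2" = N1 + (N - N1) / 2)
  }
  if (Np < 1 || Np > N) stop("turning point `Np` must lie in [1, N]")
  Np
}

#' Evaluate a time trend
#'
#' Computes `f(t)` for given arm(s) and enrolment position(s). `arm` and `t`
#' are recycled against each other.
#'
#' @param spec a [trend_spec()].
#' @param arm arm label(s) (`0` = control).
#' @param t enrolment index/time in `[1, N]`; the patient index `j` under
#'   fixed entry times.
#' @param N overall sample size (`N >= 2` for the linear and inverse-U
#'   patterns, whose slope is `1/(N - 1)`).
#' @param N1 period-1 sample size (the step location and the reference for
#'   symbolic turning points).
#' @return numeric vector of trend values on the model scale.
#' @examples
#' s <- trend_spec("step", 0.15)
#' trend_value(s, arm = 0, t = c(250, 251), N = 750, N1 = 250)  # 0, 0.15
#' @export
trend_value <- function(spec, arm, t, N, N1) {
  stopifnot(inherits(spec, "trend_spec"))
  n_out <- max(length(arm), length(t))
  arm <- rep_len(as.integer(arm), n_out)
  t <- rep_len(as.numeric(t), n_out)
  if (any(t < 1 | t > N)) stop("`t` must lie in [1, N]")
  if (spec$pattern != "step" && N < 2) {
    stop("the linear and inverse-U patterns need N >= 2")
  }
  lam <- trend_lambda(spec, arm)
  switch(spec$pattern,
    linear = lam * (t - 1) / (N - 1),
    step   = lam * (t > N1),
    inverse_u = {
      Np <- resolve_np(spec$Np, N, N1)
      if (spec$inverse_u_continuous) {
        lam * ((Np - 1) - abs(t - Np)) / (N - 1)
      } else {
        lam * (t - 1) / (N - 1) * ifelse(t <= Np, 1, -1)
      }
    })
}

#' Per-arm trend profile over the whole trial
#'
#' Evaluates the trend at every enrolment index `j = 1..N` (fixed entry
#' times) for each arm of a design. Under equal trends all columns are
#' identical.
#'
#' @param spec a [trend_spec()].
#' @param design a [trial_design()].
#' @return numeric matrix, `N` rows by one column per arm.
#' @export
trend_profile <- function(spec, design) {
  stopifnot(inherits(design, "trial_design"))
  j <- seq_len(design$N)
  N1 <- design$cutpoints[1L]
  out <- vapply(design$arms,
                function(k) trend_value(spec, k, j, design$N, N1),
                numeric(design$N))
  colnames(out) <- paste0("arm", design$arms)
  out
}
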