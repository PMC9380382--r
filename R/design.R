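#' Define a platform-trial design
#'
#' A platform trial is described by a matrix of per-arm, per-period target
#' sample sizes. Arms are labelled `0, 1, 2, ...` with arm 0 the shared
#' control; periods are maximal time spans during which the set of recruiting
#' arms does not change. In the canonical two-period design, arm 2 enters
#' after `N1` patients have been recruited, so its period-1 count is zero and
#' controls recruited in period 1 are non-concurrent with arm 2.
#'
#' @param n integer matrix of target counts, rows = arms (first row is the
#'   control, arm 0), columns = periods. Row/column names are ignored.
#'
#' @return An object of class `trial_design` with components
#'   \describe{
#'     \item{n}{the validated count matrix, `arm0..armK` by `period1..periodS`}
#'     \item{arms}{integer arm labels `0:(K)`}
#'     \item{n_periods}{number of periods `S`}
#'     \item{period_sizes}{total patients per period, `N_s`}
#'     \item{cutpoints}{cumulative patient-index cut points; patient `j`
#'       belongs to period 1 iff `j <= cutpoints[1]` (i.e. `j <= N1`)}
#'     \item{N}{overall sample size}
#'   }
#'
#' @details Validation enforces that every recruiting period contains at
#'   least one control patient, that each arm recruits over a contiguous run
#'   of periods, and that consecutive periods differ in their set of
#'   recruiting arms (otherwise the period split would not correspond to an
#'   arm entering or leaving the platform). The canonical design with
#'   `n = rbind(c(125, 125), c(125, 125), c(0, 250))` gives `N1 = 250`,
#'   `N2 = 500`, `N = 750`.
#'
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' d$cutpoints  # 250 750: arm 2 enters with patient 251
#' @export
trial_design <- function(n) {
  n <- as.matrix(n)
  if (!is.numeric(n)) {
    stop("`n` must be a numeric matrix of per-arm, per-period counts")
  }
  if (anyNA(n) || any(n < 0) || any(n != round(n))) {
    stop("all cell counts must be non-negative integers")
  }
  if (nrow(n) < 2L) {
    stop("the design needs a control arm (row 1) and at least one treatment arm")
  }
  storage.mode(n) <- "integer"
  period_sizes <- colSums(n)
  if (any(period_sizes == 0L)) {
    stop("every period must recruit at least one patient")
  }
  if (any(n[1L, ] == 0L)) {
    s <- which(n[1L, ] == 0L)[1L]
    stop(sprintf("control arm recruits no patients in period %d; every period needs concurrent controls", s))
  }
  recruiting <- n > 0L
  for (k in seq_len(nrow(n))) {
    on <- which(recruiting[k, ])
    if (length(on) && !identical(on, on[1L]:on[length(on)])) {
      stop(sprintf("arm %d recruits over non-contiguous periods", k - 1L))
    }
  }
  if (ncol(n) > 1L) {
    for (s in 2:ncol(n)) {
      if (identical(recruiting[, s], recruiting[, s - 1L])) {
        stop(sprintf(paste0(
          "periods %d and %d have the same set of recruiting arms; ",
          "periods must be delimited by an arm entering or leaving"), s - 1L, s))
      }
    }
  }
  dimnames(n) <- list(paste0("arm", seq_len(nrow(n)) - 1L),
                      paste0("period", seq_len(ncol(n))))
  structure(list(
    n = n,
    arms = seq_len(nrow(n)) - 1L,
    n_periods = ncol(n),
    period_sizes = period_sizes,
    cutpoints = cumsum(period_sizes),
    N = sum(n)
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Platform trial design:", length(x$arms), "arms,",
      x$n_periods, "periods, N =", x$N, "\n")
  print(x$n)
  invisible(x)
}

# period index for each patient 1..N (period 1 iff j <= N1, etc.)
design_periods <- function(design) {
  rep.int(seq_len(design$n_periods), design$period_sizes)
}

# sample() without the scalar surprise: permute the elements of x
resample <- function(x) x[sample.int(length(x))]

#' Generate a patient-to-arm allocation sequence
#'
#' Assigns each of the `N` patients of a design to an arm, period by period,
#' either by permuted-block randomisation or by simple randomisation.
#'
#' @param design a [trial_design()].
#' @param method `"block"` for permuted-block randomisation (the default and
#'   the recommended choice: blocking stratifies the randomisation by
#'   calendar time, which protects the step-adjusted linear model against
#'   heteroscedasticity induced by smooth time trends), or `"simple"`.
#' @param block_sizes integer block size per period (recycled if scalar).
#'   Each period's block size must yield integer per-arm block counts, i.e.
#'   be a multiple of the smallest integer vector with the period's
#'   allocation ratio (4 for 1:1, 12 for 2:1:1 with the doubled arm).
#' @param seed optional integer; if supplied, `set.seed(seed)` is called so
#'   the sequence is reproducible. If `NULL` the current RNG stream is used.
#' @param conditional for `method = "simple"`: if `TRUE` (default) the
#'   period's full arm-label multiset is randomly permuted, so realised
#'   counts equal the design targets exactly (random allocation conditional
#'   on final counts — the closed-form estimator algebra takes the cell
#'   counts as fixed). If `FALSE`, patients are assigned independently with
#'   probabilities proportional to the period targets and realised counts
#'   are random (useful to illustrate variance inflation under unrestricted
#'   randomisation).
#'
#' @return An object of class `trial_allocation`: a list with `arm` (integer
#'   vector of length `N`), `period`, `method`, `block_sizes`, `conditional`
#'   and `seed`. `as.data.frame()` turns it into a `j, period, arm` table.
#'
#' @details Under block randomisation each complete block is an independent
#'   uniformly random permutation of the per-block arm composition
#'   (`block_size * n[k, s] / N_s` patients of arm `k`). Period sizes need
#'   not be multiples of the block size: complete blocks are filled first
#'   and the period is closed with a truncated block containing a random
#'   permutation of exactly the residual per-arm counts, so realised counts
#'   always match the design.
#'
#' @examples
#' d <- trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
#' a <- allocate(d, "block", block_sizes = c(4, 12), seed = 1)
#' table(a$arm, a$period)  # reproduces the design matrix exactly
#' @export
allocate <- function(design, method = c("block", "simple"), block_sizes = NULL,
                     seed = NULL, conditional = TRUE) {
  stopifnot(inherits(design, "trial_design"))
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)

  if (method == "block") {
    if (is.null(block_sizes)) {
      stop("`block_sizes` must be given for block randomisation")
    }
    block_sizes <- as.integer(rep_len(block_sizes, design$n_periods))
    if (any(block_sizes < 1L)) stop("block sizes must be positive")
  }

  arm <- integer(0)
  for (s in seq_len(design$n_periods)) {
    counts <- design$n[, s]
    Ns <- sum(counts)
    if (method == "block") {
      bs <- block_sizes[s]
      comp <- counts * bs / Ns
      if (any(abs(comp - round(comp)) > 1e-9)) {
        stop(sprintf(
          "block size %d is incompatible with the period %d allocation ratio %s",
          bs, s, paste(counts, collapse = ":")))
      }
      comp <- as.integer(round(comp))
      n_blocks <- Ns %/% bs
      block_labels <- rep.int(design$arms, comp)
      seq_s <- unlist(lapply(seq_len(n_blocks), function(b) resample(block_labels)),
                      use.names = FALSE)
      residual <- counts - n_blocks * comp
      if (sum(residual) > 0L) {
        seq_s <- c(seq_s, resample(rep.int(design$arms, residual)))
      }
    } else if (conditional) {
      seq_s <- resample(rep.int(design$arms, counts))
    } else {
      seq_s <- sample(design$arms, Ns, replace = TRUE, prob = counts / Ns)
    }
    arm <- c(arm, seq_s)
  }

  structure(list(
    arm = arm,
    period = design_periods(design),
    method = method,
    block_sizes = if (method == "block") block_sizes else NULL,
    conditional = if (method == "simple") conditional else NA,
    seed = seed
  ), class = "trial_allocation")
}

#' @export
as.data.frame.trial_allocation <- function(x, ...) {
  data.frame(j = seq_along(x$arm), period = x$period, arm = x$arm)
}

#' @export
print.trial_allocation <- function(x, ...) {
  cat("Allocation sequence (", x$method, " randomisation), N = ",
      length(x$arm), "\n", sep = "")
  print(table(arm = x$arm, period = x$period))
  invisible(x)
}
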