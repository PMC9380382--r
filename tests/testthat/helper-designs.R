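# shared fixtures, built in code

canonical_design <- function() {
  trial_design(rbind(c(125, 125), c(125, 125), c(0, 250)))
}

small_design <- function() {
  trial_design(rbind(c(20, 20), c(20, 20), c(0, 40)))
}

# build a trial dataset directly from an arms-by-periods count matrix,
# independently of allocate(): patients are laid out period by period with
# arms in label order, and outcomes drawn iid normal around cell means
dataset_from_counts <- function(counts, means = NULL, sd = 1) {
  K <- nrow(counts); S <- ncol(counts)
  if (is.null(means)) means <- matrix(0, K, S)
  arm <- period <- integer(0)
  mu <- numeric(0)
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      arm <- c(arm, rep.int(k - 1L, counts[k, s]))
      period <- c(period, rep.int(s, counts[k, s]))
      mu <- c(mu, rep.int(means[k, s], counts[k, s]))
    }
  }
  out <- data.frame(j = seq_along(arm), t = seq_along(arm),
                    arm = arm, period = period,
                    y = rnorm(length(arm), mu, sd))
  attr(out, "endpoint") <- "continuous"
  out
}

# random cell-count matrix for the canonical 3-arm two-period layout
random_counts <- function(min = 3, max = 40) {
  rbind(c(sample(min:max, 1), sample(min:max, 1)),
        c(sample(min:max, 1), sample(min:max, 1)),
        c(0, sample(min:max, 1)))
}
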