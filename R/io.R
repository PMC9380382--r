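# Readers/writers for trial datasets and run configurations.

#' Write / read a trial dataset
#'
#' Trial datasets are stored as plain CSV with columns `j, t, arm, period,
#' y`, preceded by comment lines (`# key: value`) carrying the endpoint tag
#' and, when known, the generating seed.
#'
#' @param data a trial dataset, e.g. from [simulate_trial()].
#' @param path file path.
#' @return `write_trial_data()` returns `path` invisibly;
#'   `read_trial_data()` returns the dataset with `attr(, "endpoint")` set.
#' @export
write_trial_data <- function(data, path) {
  endpoint <- attr(data, "endpoint")
  if (is.null(endpoint)) stop("dataset has no endpoint attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ncctrends trial dataset",
               paste0("# endpoint: ", endpoint),
               if (!is.null(attr(data, "seed")))
                 paste0("# seed: ", attr(data, "seed"))), con)
  utils::write.csv(data[c("j", "t", "arm", "period", "y")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- grep("^#", header, value = TRUE)
  endpoint <- sub("^# endpoint:\\s*", "", grep("^# endpoint:", meta, value = TRUE))
  if (length(endpoint) != 1L) {
    stop("dataset file has no '# endpoint:' metadata line: ", path)
  }
  out <- utils::read.csv(path, comment.char = "#")
  required <- c("j", "arm", "period", "y")
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"t" %in% names(out)) out$t <- out$j
  bad <- which(!is.finite(out$j) | !is.finite(out$arm) |
                 !is.finite(out$period) | is.na(out$y))
  if (length(bad)) {
    stop("malformed dataset row ", bad[1L], " in ", path)
  }
  attr(out, "endpoint") <- match.arg(endpoint, c("continuous", "binary"))
  out
}

cfg_get <- function(cfg, key, required = TRUE, default = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
  val <- cfg
  for (p in parts) {
    val <- val[[p]]
    if (is.null(val)) break
  }
  if (is.null(val)) {
    if (required) stop("config: missing required key '", key, "'", call. = FALSE)
    return(default)
  }
  val
}

#' Read and validate a run configuration
#'
#' Run configurations are YAML files describing a complete, reproducible
#' simulation run. Required keys: `design.n` (list of per-arm rows of
#' period counts), `endpoint`, `trend.pattern`, `trend.lambda` (scalar or
#' one per arm), `n_reps`, `seed`, and the effect parameters for the
#' endpoint (`effects.theta1`/`effects.theta2` plus optional `effects.eta0`
#' and `effects.sigma` for continuous; `effects.p0`, `effects.OR1`,
#' `effects.OR2` for binary). Optional: `trend.Np`, `trend.entry`,
#' `randomisation.method`, `randomisation.block_sizes`, `methods`, `alpha`,
#' and a `grid` block whose entries (`pattern`, `lambda0`, `lambda1`,
#' `lambda2`, `theta2`/`OR2`) are vectors crossed into a scenario grid.
#'
#' @param path path to a YAML config file.
#' @return the validated config list, with a `design` element replaced by a
#'   [trial_design()] and defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  n <- cfg_get(cfg, "design.n")
  design <- trial_design(do.call(rbind, lapply(n, as.numeric)))
  endpoint <- match.arg(cfg_get(cfg, "endpoint"), c("continuous", "binary"))
  cfg_get(cfg, "trend.pattern")
  cfg_get(cfg, "trend.lambda")
  if (endpoint == "continuous") {
    cfg_get(cfg, "effects.theta1"); cfg_get(cfg, "effects.theta2")
  } else {
    cfg_get(cfg, "effects.p0"); cfg_get(cfg, "effects.OR1")
    cfg_get(cfg, "effects.OR2")
  }
  cfg$design <- design
  cfg$endpoint <- endpoint
  cfg$n_reps <- as.integer(cfg_get(cfg, "n_reps"))
  cfg$seed <- as.integer(cfg_get(cfg, "seed"))
  cfg$alpha <- cfg_get(cfg, "alpha", required = FALSE, default = 0.025)
  cfg$methods <- cfg_get(cfg, "methods", required = FALSE,
                         default = c("ALLTC_step", "ALLTCI_step",
                                     "pooled", "separate"))
  bad <- setdiff(cfg$methods, ncc_methods())
  if (length(bad)) stop("config: unknown method(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$randomisation)) {
    cfg$randomisation <- list(method = "block", block_sizes = c(4, 12))
  }
  cfg
}

#' Build the scenario list described by a run configuration
#'
#' @param cfg a validated config from [read_run_config()].
#' @return named list of [scenario_spec()] objects (length 1 without a
#'   `grid` block).
#' @export
config_to_scenarios <- function(cfg) {
  tr <- cfg$trend
  grid <- cfg$grid
  g_or <- function(key, default) {
    if (!is.null(grid[[key]])) unlist(grid[[key]]) else default
  }
  lambda <- rep_len(unlist(tr$lambda), 3L)
  common <- list(
    design = cfg$design, endpoint = cfg$endpoint,
    pattern = g_or("pattern", tr$pattern),
    lambda0 = g_or("lambda0", lambda[1]),
    lambda1 = g_or("lambda1", lambda[2]),
    lambda2 = g_or("lambda2", lambda[3]),
    Np = if (is.null(tr$Np)) "N1+N2/2" else tr$Np,
    entry = if (is.null(tr$entry)) "fixed" else tr$entry,
    randomisation = cfg$randomisation
  )
  eff <- cfg$effects
  args <- if (cfg$endpoint == "continuous") {
    c(common, list(
      theta1 = eff$theta1, theta2 = g_or("theta2", eff$theta2),
      eta0 = if (is.null(eff$eta0)) 0 else eff$eta0,
      sigma = if (is.null(eff$sigma)) 1 else eff$sigma))
  } else {
    c(common, list(p0 = eff$p0, OR1 = eff$OR1, OR2 = g_or("OR2", eff$OR2)))
  }
  do.call(scenario_grid, args)
}

#' Execute a run configuration
#'
#' Expands the config into scenarios and runs the full grid; the workhorse
#' behind the command-line `run` subcommand.
#'
#' @param cfg a config list from [read_run_config()] (or a path to one).
#' @param n_reps,seed optional overrides of the config values.
#' @param verbose passed to [run_grid()].
#' @return the long-format operating-characteristics table of [run_grid()].
#' @export
run_from_config <- function(cfg, n_reps = NULL, seed = NULL, verbose = TRUE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  scenarios <- config_to_scenarios(cfg)
  run_grid(scenarios, methods = cfg$methods,
           n_reps = if (is.null(n_reps)) cfg$n_reps else n_reps,
           base_seed = if (is.null(seed)) cfg$seed else seed,
           alpha = cfg$alpha, verbose = verbose)
}

#' Plot rejection-rate curves from an operating-characteristics table
#'
#' Draws rejection rate against a swept scenario parameter (by default the
#' arm-1 trend strength), one line per analysis method, faceted by trend
#' pattern when several are present. Needs ggplot2.
#'
#' @param oc a long-format results table from [run_grid()].
#' @param x name of the column to put on the x axis (default `"lambda1"`).
#' @param nominal nominal significance level drawn as a reference line
#'   (default 0.025; `NULL` to suppress).
#' @return a ggplot object.
#' @export
plot_rejection_rates <- function(oc, x = "lambda1", nominal = 0.025) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_rejection_rates() needs the ggplot2 package")
  }
  p <- ggplot2::ggplot(oc, ggplot2::aes(x = .data[[x]], y = .data$reject_rate,
                                        colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = x, y = "Rejection rate of H02", colour = "Method") +
    ggplot2::theme_bw()
  if (length(unique(oc$pattern)) > 1L) {
    p <- p + ggplot2::facet_wrap(~pattern)
  }
  if (!is.null(nominal)) {
    p <- p + ggplot2::geom_hline(yintercept = nominal, linetype = "dashed")
  }
  p
}
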