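# Run configuration: a serializable bundle of kernel, cost, drift and budget
# parameters plus the root seed, so that any analysis stage can be reproduced
# from a stored YAML file. The analysis/ drivers are thin wrappers over these.

#' Build a run configuration
#'
#' @param kernel list with `theta`, `alpha_max`, `e_max`.
#' @param cost list with `form`, `omega0_hat`.
#' @param process list with `delta_hat` (or `delta_hat_range`), `rel_sd`,
#'   `drift_scaling`.
#' @param budgets list of simulation budgets (`grid`, `n_ensembles`, `L`, and
#'   the mixture hyper-parameters).
#' @param seed root integer seed; all stage randomness derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(kernel = list(theta = 2, alpha_max = 4, e_max = 1),
                       cost = list(form = "linear", omega0_hat = 0.1),
                       process = list(delta_hat = 0.2, rel_sd = 0.05,
                                      drift_scaling = "linear"),
                       budgets = list(grid = c(50L, 50L), n_ensembles = 200L,
                                      L = 60L, beta_max = 10),
                       seed = 1L) {
  cfg <- list(kernel = kernel, cost = cost, process = process,
              budgets = budgets, seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  stopifnot(
    is.list(cfg$kernel), cfg$kernel$theta >= 0, cfg$kernel$alpha_max > 0,
    cfg$kernel$e_max > 0,
    cfg$cost$form %in% c("none", "linear", "quadratic"),
    cfg$cost$omega0_hat >= 0,
    is.numeric(cfg$seed), length(cfg$seed) == 1L
  )
  invisible(cfg)
}

#' Named parameter presets
#'
#' Parameter sets for the package's headline analyses: `"phase"` (divergence
#' scan and phase diagram: `theta = 2`, `alpha_max = 4`, `beta_max = 10`,
#' linear cost of amplitude 0.1), `"mixture"` (mixture optimization at
#' effective deliberation 2 against divergences uniform on (0, 1.6), zero
#' cost), `"lifetime35"` and `"lifetime50"` (lifetime scans at fixed
#' divergence 0.35 / 0.5), and `"demo"` (tiny smoke-test budgets).
#'
#' @param name preset name.
#' @param seed root seed stored in the config.
#' @return A [run_config()].
#' @export
preset_config <- function(name = c("phase", "mixture", "lifetime35",
                                   "lifetime50", "demo"), seed = 1L) {
  name <- match.arg(name)
  base <- run_config(seed = seed)
  switch(name,
    phase = base,
    mixture = run_config(
      cost = list(form = "none", omega0_hat = 0),
      process = list(delta_hat_range = c(0, 1.6), rel_sd = 0.05,
                     drift_scaling = "linear"),
      budgets = list(nm = 20L, beta_tilde = 2, n_restarts = 20L,
                     n_steps = 300L, n_probe = 30L, n_antigens = 50L,
                     L = 40L, epsilon = 0.1, beta_max = 10),
      seed = seed
    ),
    lifetime35 = run_config(
      process = list(delta_hat = 0.35, rel_sd = 0.05,
                     drift_scaling = "linear"),
      budgets = list(grid = c(50L, 50L), n_ensembles = 500L,
                     L_list = c(2L, 4L, 8L, 16L, 30L, 60L), beta_max = 10),
      seed = seed
    ),
    lifetime50 = run_config(
      process = list(delta_hat = 0.5, rel_sd = 0.05,
                     drift_scaling = "linear"),
      budgets = list(grid = c(50L, 50L), n_ensembles = 500L,
                     L_list = c(2L, 4L, 8L, 16L, 30L, 60L), beta_max = 10),
      seed = seed
    ),
    demo = run_config(
      budgets = list(grid = c(12L, 12L), n_ensembles = 30L, L = 20L,
                     beta_max = 10),
      seed = seed
    )
  )
}

#' Write / read a configuration as YAML
#'
#' `read_config(write_config(cfg, path))` restores the configuration exactly.
#'
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Derive a reproducible sub-seed for a named stage
#'
#' All stage randomness flows from the root seed: each (stage, index) pair
#' maps to a fixed sub-seed below 2^31, so stages are independent of the
#' order in which they run.
#'
#' @param root integer root seed.
#' @param stage stage name.
#' @param index optional within-stage index.
#' @return An integer seed.
#' @export
substream_seed <- function(root, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 7919 + h * 104729 + index * 13) %% 2147483629)
}
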