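# Run configuration: a flat, human-editable YAML mapping that bundles the
# task parameters with the sweep axes, ensemble size, seeding, and output
# location. Defaults are the package's reference parameter set
# (h = 0.75, N = 10, unit action costs, rewards (100, -100), gamma = 1).

#' Run configuration for the command-line workflow
#'
#' Builds, reads, and writes the configuration consumed by the bundled
#' command-line script (`system.file("cli", "foragedp.R", package =
#' "foragedp")`). The configuration round-trips losslessly through YAML.
#'
#' @param epsilon,q Cell coordinates for single-point commands
#'   (`simulate`, `tables`, `align`).
#' @param h,N,tau_d,tau_s,R_correct,R_incorrect,gamma Task constants, see
#'   [task_params()].
#' @param epsilon_values,q_values Sweep axes for the `sweep` command.
#' @param strategies Strategies to run.
#' @param n_realizations Ensemble size per cell per strategy.
#' @param master_seed Master seed controlling all randomness.
#' @param grid_size Belief grid size for the dynamic program.
#' @param output_dir Directory for result files.
#' @param alignment Whether sweeps also record action alignment.
#' @param driver Driver policy for alignment trajectories.
#' @return An object of class `"run_config"` (a named list).
#' @export
run_config <- function(epsilon = 0.1, q = 0.8, h = 0.75, N = 10L,
                       tau_d = 1L, tau_s = 1L,
                       R_correct = 100, R_incorrect = -100, gamma = 1,
                       epsilon_values = seq(0.025, 0.475, by = 0.025),
                       q_values = seq(0.525, 0.975, by = 0.025),
                       strategies = c("rewardmax", "infomax"),
                       n_realizations = 1000L, master_seed = 1L,
                       grid_size = 1001L, output_dir = ".",
                       alignment = FALSE, driver = "rewardmax") {
  cfg <- list(epsilon = epsilon, q = q, h = h, N = as.integer(N),
              tau_d = as.integer(tau_d), tau_s = as.integer(tau_s),
              R_correct = R_correct, R_incorrect = R_incorrect,
              gamma = gamma,
              epsilon_values = epsilon_values, q_values = q_values,
              strategies = strategies,
              n_realizations = as.integer(n_realizations),
              master_seed = as.integer(master_seed),
              grid_size = as.integer(grid_size),
              output_dir = output_dir,
              alignment = isTRUE(alignment), driver = driver)
  # validate the task-parameter slice eagerly so config errors are loud
  invisible(config_task_params(cfg))
  if (!all(cfg$strategies %in% c("rewardmax", "infomax")))
    stop("`strategies` must be a subset of rewardmax/infomax",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `"run_config"` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
config_task_params <- function(config) {
  task_params(epsilon = config$epsilon, q = config$q, h = config$h,
              N = config$N, tau_d = config$tau_d, tau_s = config$tau_s,
              R_correct = config$R_correct,
              R_incorrect = config$R_incorrect, gamma = config$gamma)
}

#' @export
print.run_config <- function(x, ...) {
  cat("foragedp run configuration\n")
  print(config_task_params(x))
  cat(sprintf("  sweep: %d x %d cells, %d realizations/cell, seed %d\n",
              length(x$epsilon_values), length(x$q_values),
              x$n_realizations, x$master_seed))
  cat(sprintf("  strategies: %s; grid size %d; output: %s\n",
              paste(x$strategies, collapse = ", "), x$grid_size,
              x$output_dir))
  invisible(x)
}
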