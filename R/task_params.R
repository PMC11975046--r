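#' Task and agent parameters
#'
#' Bundles every constant of the dynamic foraging task: the environment
#' (state-change probability, feedback reliability, evidence reliability),
#' the agent's budget and action time costs, the reward structure, and the
#' discount applied to future utility.
#'
#' @param epsilon Probability in `[0, 0.5]` that the hidden state flips
#'   after each commitment ("environmental stability" axis; small values =
#'   stable environment). Values in `(0.5, 1]` are mathematically valid and
#'   accepted with a warning, since such anti-persistent environments are
#'   outside the regime the package is designed to explore.
#' @param q Feedback reliability in `[0.5, 1]`: the probability that reward/
#'   punishment feedback matches the correctness of the decision.
#' @param h Bernoulli evidence parameter in `(0.5, 1)`: the probability that
#'   a sampled observation points at the true state.
#' @param N Positive integer time-step budget.
#' @param tau_d Positive integer time cost of a commitment.
#' @param tau_s Positive integer time cost of drawing one observation.
#' @param R_correct Reward magnitude delivered on positive feedback.
#' @param R_incorrect Reward magnitude delivered on negative feedback
#'   (typically negative).
#' @param gamma Discount in `[0, 1]` multiplying the continuation utility of
#'   each action; `gamma = 0` yields a greedy (single-action) agent.
#'
#' @return An object of class `"task_params"` (a named list).
#' @examples
#' task_params(epsilon = 0.1, q = 0.8)
#' @export
task_params <- function(epsilon, q, h = 0.75, N = 10L,
                        tau_d = 1L, tau_s = 1L,
                        R_correct = 100, R_incorrect = -100,
                        gamma = 1) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(q), length(q) == 1L,
            is.numeric(h), length(h) == 1L,
            is.numeric(N), length(N) == 1L,
            is.numeric(tau_d), length(tau_d) == 1L,
            is.numeric(tau_s), length(tau_s) == 1L,
            is.numeric(R_correct), length(R_correct) == 1L,
            is.numeric(R_incorrect), length(R_incorrect) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (epsilon < 0 || epsilon > 1)
    stop("`epsilon` must lie in [0, 1]", call. = FALSE)
  if (epsilon > 0.5)
    warning("`epsilon` > 0.5 describes an anti-persistent environment; ",
            "the mathematics is valid but untested territory", call. = FALSE)
  if (q < 0.5 || q > 1)
    stop("`q` must lie in [0.5, 1]", call. = FALSE)
  if (h <= 0.5 || h >= 1)
    stop("`h` must lie in (0.5, 1)", call. = FALSE)
  if (N != round(N) || N < 1)
    stop("`N` must be a positive integer", call. = FALSE)
  if (tau_d != round(tau_d) || tau_d < 1)
    stop("`tau_d` must be a positive integer", call. = FALSE)
  if (tau_s != round(tau_s) || tau_s < 1)
    stop("`tau_s` must be a positive integer", call. = FALSE)
  if (N < min(tau_d, tau_s))
    stop("`N` must afford at least one action: N >= min(tau_d, tau_s)",
         call. = FALSE)
  if (gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  structure(
    list(epsilon = as.numeric(epsilon), q = as.numeric(q),
         h = as.numeric(h), N = as.integer(N),
         tau_d = as.integer(tau_d), tau_s = as.integer(tau_s),
         R_correct = as.numeric(R_correct),
         R_incorrect = as.numeric(R_incorrect),
         gamma = as.numeric(gamma)),
    class = "task_params")
}

#' @export
print.task_params <- function(x, ...) {
  cat("Dynamic foraging task parameters\n")
  cat(sprintf("  change probability  epsilon = %g\n", x$epsilon))
  cat(sprintf("  feedback reliability      q = %g\n", x$q))
  cat(sprintf("  evidence reliability      h = %g\n", x$h))
  cat(sprintf("  budget N = %d, costs (tau_d, tau_s) = (%d, %d)\n",
              x$N, x$tau_d, x$tau_s))
  cat(sprintf("  rewards (R_correct, R_incorrect) = (%g, %g), gamma = %g\n",
              x$R_correct, x$R_incorrect, x$gamma))
  invisible(x)
}

# canonical string key for a parameter set (used for table caching)
#' Canonical key for a parameter set
#'
#' A short, injective, human-readable string identifying a [task_params()]
#' object (plus an optional grid size), used to key cached strategy tables
#' and to stamp output files.
#'
#' @param params A [task_params()] object.
#' @param grid_size Optional integer appended to the key.
#' @return A single string.
#' @export
params_key <- function(params, grid_size = NULL) {
  stopifnot(inherits(params, "task_params"))
  key <- sprintf("eps%s_q%s_h%s_N%d_td%d_ts%d_Rc%s_Ri%s_g%s",
                 format(params$epsilon), format(params$q), format(params$h),
                 params$N, params$tau_d, params$tau_s,
                 format(params$R_correct), format(params$R_incorrect),
                 format(params$gamma))
  if (!is.null(grid_size)) key <- sprintf("%s_G%d", key, as.integer(grid_size))
  gsub("[^A-Za-z0-9._-]", "m", key)
}
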