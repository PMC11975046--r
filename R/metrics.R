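# Behavioral and performance metrics.

#' Commit/sample burst statistics of an action sequence
#'
#' A burst is a maximal run of same-category actions (both commit
#' directions count as "commit"); runs at either end of the sequence count.
#' The summary ratio, mean sample burst length over mean commit burst
#' length, indexes the explore-exploit balance: 0 for pure exploitation
#' (no sample bursts), values above 1 for sampling-dominated behavior, and
#' an infinite sentinel if the sequence contains no commits at all.
#'
#' @param actions Character vector of actions (`"commit_plus"`,
#'   `"commit_minus"`, `"sample"`), e.g. the `action` column of a
#'   realization's events.
#' @return An object of class `"burst_stats"`: a list with
#'   `commit_bursts`, `sample_bursts` (integer run lengths),
#'   `mean_commit`, `mean_sample`, and `ratio`.
#' @examples
#' acts <- c("commit_plus", "commit_plus", "sample", "commit_minus",
#'           "sample", "commit_plus", "commit_plus", "sample",
#'           "commit_minus", "sample")
#' extract_bursts(acts)
#' @export
extract_bursts <- function(actions) {
  if (length(actions) == 0L)
    stop("`actions` must be a non-empty action sequence", call. = FALSE)
  cat_ <- ifelse(actions == "sample", "sample", "commit")
  if (any(!actions %in% c("commit_plus", "commit_minus", "sample")))
    stop("unknown action labels in `actions`", call. = FALSE)
  runs <- rle(cat_)
  commit_bursts <- runs$lengths[runs$values == "commit"]
  sample_bursts <- runs$lengths[runs$values == "sample"]
  mean_commit <- if (length(commit_bursts)) mean(commit_bursts) else NA_real_
  mean_sample <- if (length(sample_bursts)) mean(sample_bursts) else NA_real_
  ratio <- if (length(sample_bursts) == 0L) 0
  else if (length(commit_bursts) == 0L) Inf
  else mean_sample / mean_commit
  structure(list(commit_bursts = as.integer(commit_bursts),
                 sample_bursts = as.integer(sample_bursts),
                 mean_commit = mean_commit, mean_sample = mean_sample,
                 ratio = ratio),
            class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat("Burst statistics\n")
  cat("  commit bursts:", paste(x$commit_bursts, collapse = ", "), "\n")
  cat("  sample bursts:", paste(x$sample_bursts, collapse = ", "), "\n")
  cat(sprintf("  mean commit %.3g, mean sample %.3g, ratio %.3g\n",
              x$mean_commit, x$mean_sample, x$ratio))
  invisible(x)
}

# pooled burst statistics across an ensemble (bursts never span episodes)
.pooled_bursts <- function(ensemble) {
  all_commit <- integer(0); all_sample <- integer(0)
  for (r in ensemble) {
    b <- extract_bursts(r$events$action)
    all_commit <- c(all_commit, b$commit_bursts)
    all_sample <- c(all_sample, b$sample_bursts)
  }
  mean_commit <- if (length(all_commit)) mean(all_commit) else NA_real_
  mean_sample <- if (length(all_sample)) mean(all_sample) else NA_real_
  ratio <- if (length(all_sample) == 0L) 0
  else if (length(all_commit) == 0L) Inf
  else mean_sample / mean_commit
  structure(list(commit_bursts = all_commit, sample_bursts = all_sample,
                 mean_commit = mean_commit, mean_sample = mean_sample,
                 ratio = ratio),
            class = "burst_stats")
}

#' Action alignment between the two strategies
#'
#' Fraction of steps at which both policies prescribe the identical action
#' (including commit direction) given the same belief and remaining
#' budget.
#'
#' @param pairs A data frame with columns `action_rm` and `action_im`,
#'   e.g. from [simulate_aligned_pair()].
#' @return A fraction in `[0, 1]`.
#' @export
action_alignment <- function(pairs) {
  if (!all(c("action_rm", "action_im") %in% names(pairs)))
    stop("`pairs` must carry `action_rm` and `action_im` columns",
         call. = FALSE)
  if (nrow(pairs) == 0L)
    stop("`pairs` must be non-empty", call. = FALSE)
  mean(pairs$action_rm == pairs$action_im)
}

#' Empirical reward rate of one realization
#'
#' Total delivered reward divided by the time-step budget `N` (the horizon
#' is fixed, so the denominator of the reward rate is always `N`).
#'
#' @param realization A `"realization"` object.
#' @return A single reward-per-time-step value.
#' @export
empirical_reward_rate <- function(realization) {
  stopifnot(inherits(realization, "realization"))
  realization$total_reward / realization$params$N
}

#' Reward-rate distribution over an ensemble
#'
#' Collects the empirical reward rates of an ensemble (one per
#' realization) together with their mean, population standard deviation
#' (the ensemble is the full object of study, so the divisor is `n`), and
#' the robustness index `kappa = mean / sd`. A degenerate ensemble with
#' zero spread gets `kappa = +Inf` when the mean is positive, `-Inf` when
#' negative, and `NaN` at zero.
#'
#' @param x A list of `"realization"` objects, or a numeric vector of
#'   reward rates.
#' @return An object of class `"reward_rate_dist"`: a list with `rates`,
#'   `mean`, `std`, `kappa`, and `n`.
#' @export
reward_rate_dist <- function(x) {
  rates <- if (is.numeric(x)) as.numeric(x)
  else vapply(x, empirical_reward_rate, numeric(1))
  n <- length(rates)
  if (n == 0L) stop("no reward rates supplied", call. = FALSE)
  m <- mean(rates)
  s <- sqrt(mean((rates - m)^2))   # population sd
  kappa <- if (s > 0) m / s else if (m > 0) Inf else if (m < 0) -Inf else NaN
  structure(list(rates = rates, mean = m, std = s, kappa = kappa, n = n),
            class = "reward_rate_dist")
}

#' @export
print.reward_rate_dist <- function(x, ...) {
  cat(sprintf("Reward-rate distribution: n = %d, mean %.4g, sd %.4g, ",
              x$n, x$mean, x$std))
  cat(sprintf("kappa %.4g\n", x$kappa))
  invisible(x)
}

#' Normalized reward-rate differential between strategies
#'
#' `100 * (mean_rm - mean_im) / R_correct`: the average reward-rate
#' advantage of the rewardmax strategy, expressed as a percentage of one
#' correct-response reward.
#'
#' @param dist_rm,dist_im `"reward_rate_dist"` objects for the rewardmax
#'   and infomax ensembles under identical task parameters.
#' @param R_correct The correct-response reward magnitude used to
#'   normalize.
#' @return A percentage (positive when rewardmax collects more reward).
#' @export
reward_differential <- function(dist_rm, dist_im, R_correct) {
  stopifnot(inherits(dist_rm, "reward_rate_dist"),
            inherits(dist_im, "reward_rate_dist"))
  if (R_correct == 0)
    stop("`R_correct` must be nonzero", call. = FALSE)
  100 * (dist_rm$mean - dist_im$mean) / R_correct
}

#' Robustness of a reward-rate distribution
#'
#' The mean empirical reward rate divided by its (population) standard
#' deviation across the ensemble. High values mean consistently adequate
#' returns; low values mean outcomes are spread widely relative to what is
#' gained on average.
#'
#' @param dist A `"reward_rate_dist"` with at least two rates.
#' @return The robustness index `kappa`.
#' @export
robustness <- function(dist) {
  stopifnot(inherits(dist, "reward_rate_dist"))
  if (dist$n < 2L)
    stop("robustness needs at least two reward rates", call. = FALSE)
  dist$kappa
}

#' @rdname robustness
#' @param dist_rm,dist_im Distributions for the two strategies.
#' @return `robustness_differential()`: `kappa_rm - kappa_im` (negative
#'   when infomax is the more robust strategy).
#' @export
robustness_differential <- function(dist_rm, dist_im) {
  robustness(dist_rm) - robustness(dist_im)
}
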