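# Belief representation and Bayesian updates.
#
# The agent's belief about the hidden state is carried as the log-likelihood
# ratio (LLR) y = ln Pr(s+)/Pr(s-); the equivalent state likelihood is
# p = 1/(1 + exp(-y)). The LLR is the canonical representation (additive
# evidence updates, symmetric saturation); p is derived on demand. LLRs are
# clamped to +/- LLR_MAX, beyond which p is indistinguishable from 0/1 at
# double precision.

LLR_MAX <- 50

#' Convert between log-likelihood ratio and state likelihood
#'
#' The belief about the binary hidden state can be carried either as the
#' log-likelihood ratio `y = ln Pr(s+)/Pr(s-)` or as the state likelihood
#' `p = Pr(s+) = 1/(1 + exp(-y))`. These helpers map between the two;
#' both are vectorized.
#'
#' @param llr Numeric vector of log-likelihood ratios.
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @return `llr_to_prob()` returns likelihoods in `[0, 1]`;
#'   `prob_to_llr()` returns LLRs clamped to `[-50, 50]`.
#' @examples
#' llr_to_prob(0)        # 0.5
#' prob_to_llr(0.75)     # log(3)
#' @export
llr_to_prob <- function(llr) 1 / (1 + exp(-llr))

#' @rdname llr_to_prob
#' @export
prob_to_llr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  pmin(pmax(log(p) - log1p(-p), -LLR_MAX), LLR_MAX)
}

#' Evidence increment of the log-likelihood ratio
#'
#' The LLR change caused by one signed-unit observation under the Bernoulli
#' evidence model: an observation `+1` occurs with probability `h` when the
#' state is `s+` (and mirror-wise for `s-`), so it adds `log(h / (1 - h))`
#' to the LLR; an observation `-1` subtracts the same amount.
#'
#' @param obs Observation(s), each `+1` or `-1`.
#' @param h Evidence reliability in `(0, 1)`.
#' @return Numeric vector of LLR increments.
#' @examples
#' llr_increment(+1, 0.75)  # log(3)
#' @export
llr_increment <- function(obs, h) {
  if (!is.numeric(obs) || any(!obs %in% c(-1, 1)))
    stop("observations must be +1 or -1", call. = FALSE)
  if (h <= 0 || h >= 1) stop("`h` must lie in (0, 1)", call. = FALSE)
  obs * (log(h) - log1p(-h))
}

#' Within-trial belief update
#'
#' Adds the evidence increment of one observation to the current LLR
#' (observations are conditionally independent given the state, so the LLR
#' is additive). The result is clamped to `[-50, 50]`.
#'
#' @param llr Current LLR (numeric, may be vectorized).
#' @inheritParams llr_increment
#' @return Updated LLR(s).
#' @examples
#' update_belief(0, +1, 0.75)
#' @export
update_belief <- function(llr, obs, h) {
  pmin(pmax(llr + llr_increment(obs, h), -LLR_MAX), LLR_MAX)
}

# Exact Bayes carry-over of the belief across a commitment, in likelihood
# space. Returns the two posterior next-state likelihoods (one per feedback
# outcome) and the predictive probability of positive feedback.
# a = Pr(feedback = reward | s_i = s+, d): q for d = +1, 1-q for d = -1.
.commit_transition <- function(p, decision, epsilon, q) {
  a <- if (decision > 0) q else 1 - q
  # reward branch
  num_r <- p * a * (1 - epsilon) + (1 - p) * (1 - a) * epsilon
  den_r <- p * a * epsilon + (1 - p) * (1 - a) * (1 - epsilon)
  pr_reward <- p * a + (1 - p) * (1 - a)
  # punishment branch: a -> 1 - a
  num_p <- p * (1 - a) * (1 - epsilon) + (1 - p) * a * epsilon
  den_p <- p * (1 - a) * epsilon + (1 - p) * a * (1 - epsilon)
  pr_punish <- 1 - pr_reward
  p_reward <- ifelse(num_r + den_r > 0, num_r / (num_r + den_r), 0.5)
  p_punish <- ifelse(num_p + den_p > 0, num_p / (num_p + den_p), 0.5)
  list(p_reward = p_reward, p_punish = p_punish, prob_reward = pr_reward)
}

#' Prior belief carried into the next trial after a commitment
#'
#' After the agent commits to decision `d` and observes feedback `r`, the
#' belief about the *next* hidden state is the Bayesian posterior that
#' marginalizes over the current state (weighting by how well it explains
#' the feedback) and the state-change process (flip probability `epsilon`).
#' This is the exact law-of-total-probability update; when the decision
#' agrees in sign with the belief it reduces to the familiar two-branch
#' closed form with the `sign(d)` prefactor.
#'
#' @param llr Current LLR at the moment of commitment (vectorized).
#' @param decision The committed decision: `+1` (`s+`) or `-1` (`s-`).
#' @param feedback `"reward"` or `"punishment"`.
#' @param epsilon State-change probability.
#' @param q Feedback reliability.
#' @return The next-trial prior LLR, clamped to `[-50, 50]`.
#' @examples
#' prior_after_decision(0, +1, "reward", epsilon = 0.1, q = 0.8)
#' # log(0.74 / 0.26)
#' @export
prior_after_decision <- function(llr, decision, feedback, epsilon, q) {
  if (!decision %in% c(-1, 1))
    stop("`decision` must be +1 or -1", call. = FALSE)
  feedback <- match.arg(feedback, c("reward", "punishment"))
  if (epsilon < 0 || epsilon > 1) stop("`epsilon` must lie in [0, 1]",
                                       call. = FALSE)
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]", call. = FALSE)
  p <- llr_to_prob(llr)
  tr <- .commit_transition(p, decision, epsilon, q)
  p0 <- if (feedback == "reward") tr$p_reward else tr$p_punish
  prob_to_llr(p0)
}

# two-point Bayesian sampling transition in likelihood space
.sample_transition <- function(p, h) {
  w_plus <- p * h + (1 - p) * (1 - h)
  w_minus <- 1 - w_plus
  p_plus <- ifelse(w_plus > 0, h * p / w_plus, 0.5)
  p_minus <- ifelse(w_minus > 0, (1 - h) * p / w_minus, 0.5)
  list(p_plus = p_plus, p_minus = p_minus, w_plus = w_plus, w_minus = w_minus)
}

#' Predictive two-point distribution of the next state likelihood
#'
#' One more observation moves the state likelihood `p` to one of exactly two
#' values (one per observation sign), with predictive weights given by the
#' agent's own mixture over states. The mean of the returned distribution
#' equals `p` (Bayesian beliefs are martingales under the agent's
#' predictive distribution).
#'
#' @param p Current state likelihood in `[0, 1]` (scalar).
#' @param h Evidence reliability.
#' @return A data frame with columns `p_next` (the two reachable
#'   likelihoods, observation `+1` first) and `prob` (their probabilities,
#'   summing to 1).
#' @examples
#' sample_likelihood_transition(0.5, 0.75)
#' @export
sample_likelihood_transition <- function(p, h) {
  stopifnot(length(p) == 1L, length(h) == 1L)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  tr <- .sample_transition(p, h)
  data.frame(p_next = c(tr$p_plus, tr$p_minus),
             prob = c(tr$w_plus, tr$w_minus))
}

#' Environment samplers
#'
#' Draws from the three stochastic primitives of the task, using the current
#' R random number stream (seed them with `set.seed()` or use the seeded
#' simulation entry points):
#' * `feedback_sampler()` -- feedback matches decision correctness with
#'   probability `q`;
#' * `state_transition_sampler()` -- the hidden state flips with
#'   probability `epsilon` after a commitment;
#' * `evidence_sampler()` -- a signed-unit observation pointing at the true
#'   state with probability `h`.
#'
#' @param correct Logical; was the committed decision correct?
#' @param q Feedback reliability in `[0, 1]`.
#' @param s Hidden state, `+1` or `-1`.
#' @param epsilon State-change probability in `[0, 1]`.
#' @param h Evidence reliability in `[0, 1]`.
#' @return `feedback_sampler()`: `"reward"` or `"punishment"`;
#'   `state_transition_sampler()`: the next state (`+1`/`-1`);
#'   `evidence_sampler()`: an observation (`+1`/`-1`).
#' @examples
#' set.seed(1)
#' feedback_sampler(TRUE, 0.8)
#' @export
feedback_sampler <- function(correct, q) {
  stopifnot(is.logical(correct), length(correct) == 1L, q >= 0, q <= 1)
  match <- runif(1L) < q
  if (match == correct) "reward" else "punishment"
}

#' @rdname feedback_sampler
#' @export
state_transition_sampler <- function(s, epsilon) {
  stopifnot(s %in% c(-1, 1), epsilon >= 0, epsilon <= 1)
  if (runif(1L) < epsilon) -s else s
}

#' @rdname feedback_sampler
#' @export
evidence_sampler <- function(s, h) {
  stopifnot(s %in% c(-1, 1), h >= 0, h <= 1)
  if (runif(1L) < h) s else -s
}
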