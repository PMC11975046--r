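# Independent oracles and shared fixtures for the test suite.
#
# The oracles re-derive every probabilistic quantity by explicit
# enumeration over the joint outcomes (hidden state, next state, feedback,
# observation), without reusing the package's closed-form transition
# helpers, so they can serve as an independent check of the dynamic
# program and the belief updates.

entropy_ref <- function(p) {
  f <- function(x) if (x > 0) -x * log2(x) else 0
  f(p) + f(1 - p)
}

# brute-force Bayes: posterior LLR of the next state after deciding d and
# seeing feedback fb, marginalizing over the current state
oracle_prior_llr <- function(y, d, fb, eps, q) {
  p <- 1 / (1 + exp(-y))
  prior <- c(`1` = p, `-1` = 1 - p)
  post_next <- c(0, 0)   # (s' = +1, s' = -1)
  for (s in c(1, -1)) {
    p_fb <- if ((fb == "reward") == (d == s)) q else 1 - q
    w <- prior[[as.character(s)]] * p_fb
    trans_plus <- if (s == 1) 1 - eps else eps
    post_next[1] <- post_next[1] + w * trans_plus
    post_next[2] <- post_next[2] + w * (1 - trans_plus)
  }
  log(post_next[1]) - log(post_next[2])
}

# exhaustive expectimax over all action/outcome branches, on exact belief
# values (no grid). Slot convention: actions occupy slots 1..N; an action
# of cost tau at slot k is applicable when k + tau - 1 <= N; slot N is the
# boundary (one-shot commit for rewardmax, 0 for infomax); continuations
# indexed past N are worth 0.
oracle_value <- function(strategy, p, k, pars) {
  N <- pars$N; eps <- pars$epsilon; q <- pars$q; h <- pars$h
  gamma <- pars$gamma
  commit_branch <- function(p, d) {
    # returns list(prob, p0) over feedback outcomes with prob > 0
    out <- list()
    for (fb in c("reward", "punishment")) {
      pr <- 0; num <- 0
      for (s in c(1, -1)) {
        ps <- if (s == 1) p else 1 - p
        p_fb <- if ((fb == "reward") == (d == s)) q else 1 - q
        pr <- pr + ps * p_fb
        num <- num + ps * p_fb * (if (s == 1) 1 - eps else eps)
      }
      if (pr > 0) out[[fb]] <- list(prob = pr, p0 = num / pr)
    }
    out
  }
  sample_branch <- function(p) {
    out <- list()
    for (xi in c(1, -1)) {
      pr <- 0; num <- 0
      for (s in c(1, -1)) {
        ps <- if (s == 1) p else 1 - p
        p_xi <- if (xi == s) h else 1 - h
        pr <- pr + ps * p_xi
        if (s == 1) num <- num + ps * p_xi
      }
      if (pr > 0) out[[as.character(xi)]] <- list(prob = pr, p0 = num / pr)
    }
    out
  }
  commit_expectation <- function(p, d) {
    pr_reward <- p * (if (d == 1) q else 1 - q) +
      (1 - p) * (if (d == 1) 1 - q else q)
    pr_reward * pars$R_correct + (1 - pr_reward) * pars$R_incorrect
  }
  if (k > N) return(0)
  if (k == N) {
    if (strategy == "rewardmax")
      return(max(commit_expectation(p, 1), commit_expectation(p, -1)))
    return(0)
  }
  vals <- numeric(0)
  if (k + pars$tau_d - 1 <= N) {
    for (d in c(1, -1)) {
      br <- commit_branch(p, d)
      if (strategy == "rewardmax") {
        v <- commit_expectation(p, d)
        for (b in br)
          v <- v + gamma * b$prob *
            oracle_value(strategy, b$p0, k + pars$tau_d, pars)
      } else {
        pbar <- p * (1 - eps) + (1 - p) * eps
        v <- entropy_ref(pbar)
        for (b in br)
          v <- v + b$prob *
            (-entropy_ref(b$p0) +
               gamma * oracle_value(strategy, b$p0, k + pars$tau_d, pars))
      }
      vals <- c(vals, v)
    }
  }
  if (k + pars$tau_s - 1 <= N) {
    br <- sample_branch(p)
    v <- if (strategy == "infomax") entropy_ref(p) else 0
    for (b in br)
      v <- v + b$prob *
        ((if (strategy == "infomax") -entropy_ref(b$p0) else 0) +
           gamma * oracle_value(strategy, b$p0, k + pars$tau_s, pars))
    vals <- c(vals, v)
  }
  if (length(vals) == 0L) return(0)
  max(vals)
}

# replay a realization's recorded beliefs through the exported belief
# updates; returns the recomputed llr_after sequence
replay_llr <- function(real) {
  ev <- real$events
  pars <- real$params
  llr <- 0
  out <- numeric(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    stopifnot(abs(ev$llr_before[i] - llr) < 1e-12)
    if (ev$action[i] == "sample") {
      llr <- update_belief(llr, ev$observation[i], pars$h)
    } else {
      d <- if (ev$action[i] == "commit_plus") 1 else -1
      llr <- prior_after_decision(llr, d, ev$feedback[i],
                                  pars$epsilon, pars$q)
    }
    out[i] <- llr
  }
  out
}

# forward enumeration of the (belief, slot) pairs an episode can visit:
# slot 1 holds the uninformative prior; each applicable action maps a pair
# to its successor pairs at slot k + tau
reachable_pairs <- function(pars) {
  N <- pars$N
  pairs <- list(c(p = 0.5, k = 1))
  seen <- c("0.5|1")
  i <- 1L
  while (i <= length(pairs)) {
    p <- unname(pairs[[i]]["p"]); k <- unname(pairs[[i]]["k"])
    succ <- list()
    if (k + pars$tau_d - 1 <= N && k + pars$tau_d <= N) {
      tr_p <- foragedp:::.commit_transition(p, 1, pars$epsilon, pars$q)
      tr_m <- foragedp:::.commit_transition(p, -1, pars$epsilon, pars$q)
      for (v in c(tr_p$p_reward, tr_p$p_punish, tr_m$p_reward,
                  tr_m$p_punish))
        succ <- c(succ, list(c(p = v, k = k + pars$tau_d)))
    }
    if (k + pars$tau_s - 1 <= N && k + pars$tau_s <= N) {
      tr_s <- foragedp:::.sample_transition(p, pars$h)
      for (v in c(tr_s$p_plus, tr_s$p_minus))
        succ <- c(succ, list(c(p = v, k = k + pars$tau_s)))
    }
    for (s in succ) {
      key <- paste(format(s["p"], digits = 17), s["k"], sep = "|")
      if (!key %in% seen) {
        seen <- c(seen, key)
        pairs <- c(pairs, list(s))
      }
    }
    i <- i + 1L
  }
  do.call(rbind, lapply(pairs, function(x)
    data.frame(p = unname(x["p"]), k = unname(x["k"]))))
}

# memoised table builder shared across test files
.tab_cache <- new.env(parent = emptyenv())
cached_tables <- function(strategy, pars, grid_size = 1001L,
                          extra_knots = NULL) {
  key <- paste(strategy, params_key(pars, grid_size),
               length(extra_knots), sep = "|")
  if (is.null(.tab_cache[[key]]))
    .tab_cache[[key]] <- build_tables(strategy, pars,
                                      grid_size = grid_size,
                                      extra_knots = extra_knots)
  .tab_cache[[key]]
}
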