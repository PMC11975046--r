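# Seeded agent-environment episodes.
#
# RNG contract: every entry point takes an explicit integer seed; ensembles
# fan one master seed out into per-realization seeds via sample.int, so
# realization i is reproducible independently of how many others are run.
# Within a realization the draw order is fixed: (1) initial hidden state;
# then per action: one tie-break coin (consumed every step, used only on
# exact policy ties), followed by the outcome draw(s) (observation for a
# sample; feedback match and state flip for a commit).

.derive_seeds <- function(master_seed, n) {
  stopifnot(length(master_seed) == 1L, master_seed == round(master_seed))
  set.seed(as.integer(master_seed))
  sample.int(2147483646L, n)
}

.same_params <- function(a, b) {
  identical(params_key(a), params_key(b))
}

# core episode loop. `passive` optionally carries a second strategy's
# tables queried at every step without influencing the trajectory; a
# direction tie at p = 0.5 consumes one shared coin per step so both
# policies resolve it identically.
.sim_core <- function(tables, seed, passive = NULL) {
  params <- tables$params
  N <- params$N; tau_d <- params$tau_d; tau_s <- params$tau_s
  eps <- params$epsilon; q <- params$q; h <- params$h
  Rc <- params$R_correct; Ri <- params$R_incorrect
  grid <- tables$grid
  Qcp <- tables$Q$commit_plus; Qcm <- tables$Q$commit_minus
  Qsm <- tables$Q$sample
  if (!is.null(passive)) {
    pg <- passive$grid
    PQcp <- passive$Q$commit_plus; PQcm <- passive$Q$commit_minus
    PQsm <- passive$Q$sample
  }
  lh <- log(h) - log1p(-h)

  set.seed(as.integer(seed))
  state <- if (runif(1L) < 0.5) 1 else -1
  llr <- 0; k <- 1L; step <- 0L   # actions occupy slots 1..N
  nmax <- N %/% min(tau_d, tau_s)
  k_v <- integer(nmax); st_v <- numeric(nmax); act_v <- integer(nmax)
  obs_v <- rep(NA_real_, nmax); fb_v <- rep(NA_character_, nmax)
  lb_v <- numeric(nmax); la_v <- numeric(nmax); rew_v <- numeric(nmax)
  pact_v <- integer(nmax)

  pick <- function(qcp, qcm, qs, feas_c, feas_s, p, coin) {
    if (!feas_c) return(3L)
    qc <- max(qcp, qcm)
    if (feas_s) {
      tol <- 1e-9 * (1 + max(abs(qc), abs(qs)))
      if (qs > qc + tol) return(3L)
    }
    tolc <- 1e-9 * (1 + max(abs(qcp), abs(qcm)))
    if (qcp > qcm + tolc) 1L
    else if (qcm > qcp + tolc) 2L
    else if (p > 0.5) 1L
    else if (p < 0.5) 2L
    else if (coin) 1L else 2L
  }

  repeat {
    feas_c <- (k + tau_d - 1L) <= N
    feas_s <- (k + tau_s - 1L) <= N
    if (!feas_c && !feas_s) break
    p <- 1 / (1 + exp(-llr))
    col <- k + 1L
    i <- findInterval(p, grid, all.inside = TRUE)
    t <- (p - grid[i]) / (grid[i + 1L] - grid[i])
    qcp <- Qcp[i, col] + t * (Qcp[i + 1L, col] - Qcp[i, col])
    qcm <- Qcm[i, col] + t * (Qcm[i + 1L, col] - Qcm[i, col])
    qs <- if (is.finite(Qsm[i, col]) && is.finite(Qsm[i + 1L, col]))
      Qsm[i, col] + t * (Qsm[i + 1L, col] - Qsm[i, col]) else -Inf
    coin <- runif(1L) < 0.5   # one shared tie coin per step
    act <- pick(qcp, qcm, qs, feas_c, feas_s, p, coin)
    if (!is.null(passive)) {
      j <- findInterval(p, pg, all.inside = TRUE)
      tp <- (p - pg[j]) / (pg[j + 1L] - pg[j])
      pqcp <- PQcp[j, col] + tp * (PQcp[j + 1L, col] - PQcp[j, col])
      pqcm <- PQcm[j, col] + tp * (PQcm[j + 1L, col] - PQcm[j, col])
      pqs <- if (is.finite(PQsm[j, col]) && is.finite(PQsm[j + 1L, col]))
        PQsm[j, col] + tp * (PQsm[j + 1L, col] - PQsm[j, col]) else -Inf
      pact <- pick(pqcp, pqcm, pqs, feas_c, feas_s, p, coin)
    } else pact <- NA_integer_

    step <- step + 1L
    k_v[step] <- k; st_v[step] <- state; lb_v[step] <- llr
    act_v[step] <- act; pact_v[step] <- pact
    if (act == 3L) {
      obs <- if (runif(1L) < h) state else -state
      llr <- min(max(llr + obs * lh, -LLR_MAX), LLR_MAX)
      obs_v[step] <- obs
      k <- k + tau_s
    } else {
      d <- if (act == 1L) 1 else -1
      correct <- (d == state)
      match <- runif(1L) < q
      rewarded <- (match == correct)
      fb_v[step] <- if (rewarded) "reward" else "punishment"
      rew_v[step] <- if (rewarded) Rc else Ri
      tr <- .commit_transition(1 / (1 + exp(-llr)), d, eps, q)
      p0 <- if (rewarded) tr$p_reward else tr$p_punish
      llr <- prob_to_llr(p0)
      if (runif(1L) < eps) state <- -state
      k <- k + tau_d
    }
    la_v[step] <- llr
  }

  idx <- seq_len(step)
  events <- structure(
    list(k = k_v[idx], state = st_v[idx],
         action = .action_label(act_v[idx]),
         observation = obs_v[idx], feedback = fb_v[idx],
         llr_before = lb_v[idx], llr_after = la_v[idx],
         reward = rew_v[idx]),
    class = "data.frame", row.names = idx)
  list(events = events, total_reward = sum(rew_v[idx]),
       passive_action = .action_label(pact_v[idx]),
       k_end = k)
}

#' Simulate one seeded episode
#'
#' Runs a full budget-length episode of the foraging task under the
#' policy stored in `tables`: the belief starts at the uninformative prior
#' (LLR 0), the hidden state is drawn uniformly, and the agent alternates
#' policy queries with environment responses. A sample action draws an
#' observation and updates the belief within the trial; a commit scores the
#' decision against the hidden state, draws feedback, delivers the reward
#' attached to the feedback sign, carries the belief over as the next
#' trial's prior, and lets the state flip with probability `epsilon`. An
#' action is initiated only while its time cost fits in the remaining
#' budget. Fully reproducible from `seed`.
#'
#' @param tables A `"strategy_tables"` object from [build_tables()].
#' @param seed Integer seed for this episode.
#' @param params Optional [task_params()]; if supplied it must match
#'   `tables$params` (a mismatch is a configuration error).
#' @return An object of class `"realization"`: a list with `params`,
#'   `strategy`, `seed`, `events` (one row per action: time index, hidden
#'   state, action, observation or feedback, belief before/after as LLR,
#'   reward delivered), and `total_reward`.
#' @examples
#' pars <- task_params(epsilon = 0.1, q = 0.8, N = 10)
#' tab <- build_tables("rewardmax", pars, grid_size = 201)
#' sim <- simulate_realization(tab, seed = 7)
#' sim$events
#' @export
simulate_realization <- function(tables, seed, params = NULL) {
  .check_tables(tables)
  if (!is.null(params)) {
    stopifnot(inherits(params, "task_params"))
    if (!.same_params(params, tables$params))
      stop("`params` does not match the parameters the tables were built ",
           "with", call. = FALSE)
  }
  core <- .sim_core(tables, seed)
  structure(list(params = tables$params, strategy = tables$strategy,
                 seed = as.integer(seed), events = core$events,
                 total_reward = core$total_reward),
            class = "realization")
}

#' @export
print.realization <- function(x, ...) {
  cat(sprintf("Foraging realization (%s, seed %d)\n", x$strategy, x$seed))
  cat(sprintf("  %d actions, total reward %g, empirical rate %g\n",
              nrow(x$events), x$total_reward,
              x$total_reward / x$params$N))
  invisible(x)
}

#' Simulate a seeded ensemble of episodes
#'
#' Runs `n` independent realizations whose seeds are derived from one
#' master seed, so the ensemble is reproducible as a whole and each member
#' is reproducible on its own.
#'
#' @inheritParams simulate_realization
#' @param n Number of realizations.
#' @param master_seed Integer master seed.
#' @return A list of `"realization"` objects.
#' @export
simulate_ensemble <- function(tables, n, master_seed, params = NULL) {
  stopifnot(n >= 1)
  seeds <- .derive_seeds(master_seed, n)
  lapply(seeds, function(s) simulate_realization(tables, s, params = params))
}

#' Paired policy queries along shared belief trajectories
#'
#' Generates `n` episodes in which one strategy (the `driver`) chooses the
#' actions that advance the environment, while the other strategy is
#' queried passively at every step with the identical belief and remaining
#' budget. Each step therefore yields a pair of prescribed actions under
#' the same conditions, the raw material for the action-alignment metric.
#' A commit-direction tie at `p = 0.5` consumes one shared coin per step,
#' so both policies resolve exact indifference identically.
#'
#' @param tables_rm Rewardmax `"strategy_tables"`.
#' @param tables_im Infomax `"strategy_tables"`.
#' @param driver Which policy's actions drive the trajectory.
#' @param n Number of shared trajectories.
#' @param master_seed Integer master seed.
#' @param params Optional [task_params()] cross-check.
#' @return A data frame of class `"aligned_actions"` with columns
#'   `realization`, `step`, `k`, `p`, `action_rm`, `action_im`, and a
#'   `driver` attribute.
#' @export
simulate_aligned_pair <- function(tables_rm, tables_im,
                                  driver = c("rewardmax", "infomax"),
                                  n, master_seed, params = NULL) {
  driver <- match.arg(driver)
  .check_tables(tables_rm); .check_tables(tables_im)
  if (tables_rm$strategy != "rewardmax" || tables_im$strategy != "infomax")
    stop("pass a rewardmax table and an infomax table, in that order",
         call. = FALSE)
  if (!.same_params(tables_rm$params, tables_im$params))
    stop("the two tables were built with different task parameters",
         call. = FALSE)
  if (!is.null(params) && !.same_params(params, tables_rm$params))
    stop("`params` does not match the tables", call. = FALSE)
  seeds <- .derive_seeds(master_seed, n)
  drv <- if (driver == "rewardmax") tables_rm else tables_im
  pas <- if (driver == "rewardmax") tables_im else tables_rm
  rows <- lapply(seq_len(n), function(i) {
    core <- .sim_core(drv, seeds[i], passive = pas)
    ev <- core$events
    drv_act <- ev$action
    pas_act <- core$passive_action
    data.frame(realization = i, step = seq_len(nrow(ev)), k = ev$k,
               p = llr_to_prob(ev$llr_before),
               action_rm = if (driver == "rewardmax") drv_act else pas_act,
               action_im = if (driver == "rewardmax") pas_act else drv_act)
  })
  out <- do.call(rbind, rows)
  attr(out, "driver") <- driver
  class(out) <- c("aligned_actions", "data.frame")
  out
}

#' Export realization events to CSV
#'
#' Writes the tidy one-row-per-event table of a realization, stamped with
#' the parameter key and seed for provenance.
#'
#' @param x A `"realization"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_realization_csv <- function(x, path) {
  stopifnot(inherits(x, "realization"))
  ev <- x$events
  ev$seed <- x$seed
  ev$strategy <- x$strategy
  ev$params_key <- params_key(x$params)
  write.csv(ev, path, row.names = FALSE)
  invisible(path)
}
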