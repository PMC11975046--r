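# Finite-horizon backward induction over a discretized belief space.
#
# Both strategies share the same mechanics: at each time step k (0..N) and
# each belief p, the agent compares the utility of committing to either
# alternative against the utility of drawing one more observation, where
# each action's utility is its immediate objective gain plus the
# gamma-discounted table value at the belief the action leads to (evaluated
# at time k + tau for that action's cost tau). Time indexing: columns run
# k = 0..N, where k is the 1-based action slot within the budget -- an
# action at slot k occupies time steps k..k+tau-1, so it is applicable when
# k + tau - 1 <= N, and a simulated episode occupies slots 1..N (exactly N
# actions under unit costs; column 0 is the value of one hypothetical extra
# slot). The terminal column N holds the boundary value: the one-shot
# commit expectation for rewardmax ("nothing to gain from one more
# observation"), identically 0 for infomax (no future information gain is
# possible), and it prescribes a commit. Continuation values indexed past N
# are truncated to zero. Off-grid lookups interpolate linearly in
# likelihood space; utilities are exact wherever a belief and all its
# successors are grid knots (see `reachable_beliefs()`).

# action codes used in the tables
ACTION_LEVELS <- c("commit_plus", "commit_minus", "sample", "commit_either")

.action_label <- function(code) {
  out <- rep(NA_character_, length(code))
  out[!is.na(code) & code == 1L] <- "commit_plus"
  out[!is.na(code) & code == 2L] <- "commit_minus"
  out[!is.na(code) & code == 3L] <- "sample"
  out[!is.na(code) & code == 0L] <- "commit_either"
  out
}

#' Binary entropy in bits
#'
#' Shannon entropy of a Bernoulli state distribution,
#' `H(p) = -p log2 p - (1-p) log2(1-p)`, with the convention
#' `0 log2 0 = 0`. This is the uncertainty the infomax agent acts to reduce.
#'
#' @param p Probability vector in `[0, 1]`.
#' @return Entropy values in bits, in `[0, 1]`.
#' @examples
#' binary_entropy(c(0, 0.5, 0.75, 1))
#' @export
binary_entropy <- function(p) {
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(p, 0), 1)
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  term(p) + term(1 - p)
}

#' One-shot commit expectation at the end of the budget
#'
#' The rewardmax boundary value: with no time left for further actions, the
#' utility of belief `p` is the larger of the two commit expectations,
#' `max_d { Pr(reward | d, p) R_correct + Pr(punishment | d, p) R_incorrect }`,
#' where feedback matches correctness with probability `q`.
#'
#' @param p State likelihood vector in `[0, 1]`.
#' @param params A [task_params()] object.
#' @return Numeric vector of terminal utilities.
#' @examples
#' pars <- task_params(epsilon = 0.1, q = 0.8)
#' rewardmax_terminal_utility(c(0.5, 0.9, 1), pars)
#' @export
rewardmax_terminal_utility <- function(p, params) {
  stopifnot(inherits(params, "task_params"))
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  q <- params$q
  pr_plus <- q * p + (1 - q) * (1 - p)        # Pr(reward | commit s+)
  u_plus <- pr_plus * params$R_correct + (1 - pr_plus) * params$R_incorrect
  pr_minus <- 1 - pr_plus
  u_minus <- pr_minus * params$R_correct + (1 - pr_minus) * params$R_incorrect
  pmax(u_plus, u_minus)
}

# linear interpolation on a sorted grid; exact at knots
.interp_grid <- function(grid, values, x) {
  i <- findInterval(x, grid, all.inside = TRUE)
  dx <- grid[i + 1L] - grid[i]
  t <- (x - grid[i]) / dx
  values[i] + t * (values[i + 1L] - values[i])
}

# action-utility components at a vector of beliefs, for table construction.
# lookup(x, kk) must return the continuation utility at beliefs x and time
# kk, or zeros when kk > N (budget overrun truncates the continuation only).
.action_utilities <- function(strategy, p, k, params, lookup) {
  eps <- params$epsilon; q <- params$q; h <- params$h
  gamma <- params$gamma
  trp <- .commit_transition(p, +1, eps, q)
  trm <- .commit_transition(p, -1, eps, q)
  trs <- .sample_transition(p, h)
  kd <- k + params$tau_d
  ks <- k + params$tau_s
  Vrp <- lookup(trp$p_reward, kd); Vpp <- lookup(trp$p_punish, kd)
  Vrm <- lookup(trm$p_reward, kd); Vpm <- lookup(trm$p_punish, kd)
  Vsp <- lookup(trs$p_plus, ks); Vsm <- lookup(trs$p_minus, ks)
  if (strategy == "rewardmax") {
    imm_cp <- trp$prob_reward * params$R_correct +
      (1 - trp$prob_reward) * params$R_incorrect
    imm_cm <- trm$prob_reward * params$R_correct +
      (1 - trm$prob_reward) * params$R_incorrect
    imm_s <- 0
  } else {
    pbar <- p + eps - 2 * p * eps   # next-state marginal (q = 0.5 baseline)
    base <- binary_entropy(pbar)
    imm_cp <- base - (trp$prob_reward * binary_entropy(trp$p_reward) +
                        (1 - trp$prob_reward) * binary_entropy(trp$p_punish))
    imm_cm <- base - (trm$prob_reward * binary_entropy(trm$p_reward) +
                        (1 - trm$prob_reward) * binary_entropy(trm$p_punish))
    imm_s <- binary_entropy(p) -
      (trs$w_plus * binary_entropy(trs$p_plus) +
         trs$w_minus * binary_entropy(trs$p_minus))
  }
  list(
    commit_plus = imm_cp + gamma * (trp$prob_reward * Vrp +
                                      (1 - trp$prob_reward) * Vpp),
    commit_minus = imm_cm + gamma * (trm$prob_reward * Vrm +
                                       (1 - trm$prob_reward) * Vpm),
    sample = imm_s + gamma * (trs$w_plus * Vsp + trs$w_minus * Vsm))
}

# vectorized argmax with the documented tie rules:
#  - commit beats sample on (near-)exact ties;
#  - commit direction follows the belief; an exact direction tie at
#    p = 0.5 is marked 0L ("commit_either") and resolved by a fair coin at
#    query time so that ensemble statistics stay symmetric.
.choose_actions <- function(qcp, qcm, qs, feas_c, feas_s, p,
                            tol_scale = 1e-9) {
  n <- length(p)
  if (!feas_c && !feas_s)
    return(list(action = rep(NA_integer_, n), utility = numeric(n)))
  if (!feas_c)
    return(list(action = rep(3L, n), utility = qs))
  qc <- pmax(qcp, qcm)
  tolc <- tol_scale * (1 + pmax(abs(qcp), abs(qcm)))
  dir <- ifelse(qcp > qcm + tolc, 1L,
                ifelse(qcm > qcp + tolc, 2L,
                       ifelse(p > 0.5, 1L, ifelse(p < 0.5, 2L, 0L))))
  if (!feas_s)
    return(list(action = dir, utility = qc))
  tol <- tol_scale * (1 + pmax(abs(qc), abs(qs)))
  take_s <- qs > qc + tol
  list(action = ifelse(take_s, 3L, dir),
       utility = ifelse(take_s, qs, qc))
}

#' Beliefs reachable within the budget
#'
#' Enumerates every state likelihood the agent can hold during an episode:
#' starting from the uninformative prior, closes the set under the
#' two-point sampling transition and the four commit/feedback carry-over
#' transitions, for as many actions as the budget affords. Useful as extra
#' grid knots for [build_tables()]: when every reachable belief is a knot,
#' the backward induction is exact (no interpolation error) at all of them.
#' The set grows combinatorially, so enumeration is refused for large
#' budgets.
#'
#' @param params A [task_params()] object (small `N`).
#' @param p0 Starting likelihood (default 0.5).
#' @param max_points Safety cap on the set size.
#' @return Sorted numeric vector of reachable likelihoods.
#' @export
reachable_beliefs <- function(params, p0 = 0.5, max_points = 50000L) {
  stopifnot(inherits(params, "task_params"))
  n_actions <- params$N %/% min(params$tau_d, params$tau_s)
  pts <- p0
  frontier <- p0
  for (step in seq_len(n_actions)) {
    trp <- .commit_transition(frontier, +1, params$epsilon, params$q)
    trm <- .commit_transition(frontier, -1, params$epsilon, params$q)
    trs <- .sample_transition(frontier, params$h)
    nxt <- unique(c(trp$p_reward, trp$p_punish, trm$p_reward, trm$p_punish,
                    trs$p_plus, trs$p_minus))
    frontier <- setdiff(nxt, pts)
    pts <- c(pts, frontier)
    if (length(pts) > max_points)
      stop("reachable belief set exceeds `max_points`; ",
           "enumeration is intended for small budgets", call. = FALSE)
    if (length(frontier) == 0L) break
  }
  sort(unique(pts))
}

#' Build strategy tables by backward induction
#'
#' Fills the utility and action tables of one strategy over a likelihood
#' grid and the time-step budget, by Bellman backward induction from the
#' terminal boundary (one-shot commit expectation for rewardmax; zero for
#' infomax, since no future information gain is possible). Columns index
#' the action slot `k = 0..N`: an action at slot `k` occupies time steps
#' `k..k+tau-1` and is applicable when `k + tau - 1 <= N`; episodes occupy
#' slots `1..N`. At every `(belief, k)` the stored action attains the
#' maximum utility among the applicable actions; continuation values
#' landing beyond the budget are truncated to zero. Off-grid continuation
#' beliefs are linearly interpolated.
#'
#' @param strategy `"rewardmax"` or `"infomax"`.
#' @param params A [task_params()] object.
#' @param grid_size Number of uniform likelihood grid points (default 1001).
#' @param extra_knots Optional additional likelihood values inserted into
#'   the grid (e.g. [reachable_beliefs()] for an exact small-budget table).
#' @return An object of class `"strategy_tables"`: a list with elements
#'   `strategy`, `params`, `grid`, `utility` (matrix, grid x time 0..N),
#'   `action` (integer codes, same shape), and `Q` (per-action utility
#'   matrices `commit_plus`, `commit_minus`, `sample`).
#' @examples
#' pars <- task_params(epsilon = 0.1, q = 0.8, N = 5)
#' tab <- build_tables("rewardmax", pars, grid_size = 201)
#' tab
#' @export
build_tables <- function(strategy = c("rewardmax", "infomax"), params,
                         grid_size = 1001L, extra_knots = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(params, "task_params"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 2L) stop("`grid_size` must be at least 2", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_size)
  if (!is.null(extra_knots)) {
    if (any(extra_knots < 0 | extra_knots > 1))
      stop("`extra_knots` must lie in [0, 1]", call. = FALSE)
    grid <- sort(unique(c(grid, as.numeric(extra_knots))))
  }
  G <- length(grid)
  N <- params$N
  U <- matrix(0, G, N + 1L)
  A <- matrix(NA_integer_, G, N + 1L)
  Qcp <- Qcm <- Qs <- matrix(NA_real_, G, N + 1L)

  # terminal boundary (time step N)
  zero_lookup <- function(x, kk) numeric(length(x))
  term <- .action_utilities(strategy, grid, N, params,
                            lookup = zero_lookup)
  if (strategy == "rewardmax") {
    Qcp[, N + 1L] <- term$commit_plus
    Qcm[, N + 1L] <- term$commit_minus
  } else {
    Qcp[, N + 1L] <- 0
    Qcm[, N + 1L] <- 0
  }
  Qs[, N + 1L] <- -Inf
  sel <- .choose_actions(Qcp[, N + 1L], Qcm[, N + 1L], Qs[, N + 1L],
                         feas_c = TRUE, feas_s = FALSE, p = grid)
  U[, N + 1L] <- sel$utility
  A[, N + 1L] <- sel$action

  lookup <- function(x, kk) {
    if (kk > N) return(numeric(length(x)))
    .interp_grid(grid, U[, kk + 1L], x)
  }
  for (k in seq.int(N - 1L, 0L)) {
    util <- .action_utilities(strategy, grid, k, params, lookup = lookup)
    col <- k + 1L
    Qcp[, col] <- util$commit_plus
    Qcm[, col] <- util$commit_minus
    Qs[, col] <- util$sample
    feas_c <- (k + params$tau_d - 1L) <= N
    feas_s <- (k + params$tau_s - 1L) <= N
    sel <- .choose_actions(Qcp[, col], Qcm[, col], Qs[, col],
                           feas_c = feas_c, feas_s = feas_s, p = grid)
    U[, col] <- sel$utility
    A[, col] <- sel$action
  }
  structure(list(strategy = strategy, params = params, grid = grid,
                 grid_size = grid_size, utility = U, action = A,
                 Q = list(commit_plus = Qcp, commit_minus = Qcm,
                          sample = Qs)),
            class = "strategy_tables")
}

.check_tables <- function(tables) {
  if (!inherits(tables, "strategy_tables"))
    stop("`tables` must be built with build_tables()", call. = FALSE)
}

.check_k <- function(tables, k) {
  if (length(k) != 1L || k != round(k) || k < 0 || k > tables$params$N)
    stop("`k` must be an integer time step in [0, N]", call. = FALSE)
}

# interpolated per-action utilities at a single (p, k)
.q_at <- function(tables, p, k) {
  col <- as.integer(k) + 1L
  g <- tables$grid
  i <- findInterval(p, g, all.inside = TRUE)
  t <- (p - g[i]) / (g[i + 1L] - g[i])
  lerp <- function(M) {
    a <- M[i, col]; b <- M[i + 1L, col]
    if (!is.finite(a) || !is.finite(b)) return(-Inf)  # barred action
    a + t * (b - a)
  }
  c(commit_plus = lerp(tables$Q$commit_plus),
    commit_minus = lerp(tables$Q$commit_minus),
    sample = lerp(tables$Q$sample))
}

#' Per-action utilities from a filled table
#'
#' Interpolated utility of one concrete action at belief `p` and time step
#' `k`, read from a table built by [build_tables()]: the immediate
#' objective gain (expected reward for rewardmax; baseline-normalized
#' entropy reduction for infomax) plus the discounted continuation utility
#' at the belief the action leads to. `*_commit_utility()` takes a
#' `direction` (`+1` or `-1`); `*_sample_utility()` is the evidence-drawing
#' branch. The functions check that the table belongs to the matching
#' strategy.
#'
#' @param tables A `"strategy_tables"` object of the matching strategy.
#' @param p State likelihood in `[0, 1]`.
#' @param k Integer time step in `[0, N]` (for `k = N` the stored boundary
#'   values are returned).
#' @param direction Commit direction, `+1` for `s+` or `-1` for `s-`.
#' @return A single utility value.
#' @examples
#' pars <- task_params(epsilon = 0.1, q = 0.8, N = 5)
#' tab <- build_tables("rewardmax", pars, grid_size = 201)
#' rewardmax_commit_utility(tab, p = 0.7, k = 2, direction = +1)
#' rewardmax_sample_utility(tab, p = 0.7, k = 2)
#' @export
rewardmax_commit_utility <- function(tables, p, k, direction = +1) {
  .check_tables(tables); .check_k(tables, k)
  if (tables$strategy != "rewardmax")
    stop("`tables` is not a rewardmax table", call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("`direction` must be +1 or -1", call. = FALSE)
  qv <- .q_at(tables, p, k)
  unname(if (direction > 0) qv["commit_plus"] else qv["commit_minus"])
}

#' @rdname rewardmax_commit_utility
#' @export
rewardmax_sample_utility <- function(tables, p, k) {
  .check_tables(tables); .check_k(tables, k)
  if (tables$strategy != "rewardmax")
    stop("`tables` is not a rewardmax table", call. = FALSE)
  unname(.q_at(tables, p, k)["sample"])
}

#' @rdname rewardmax_commit_utility
#' @export
infomax_commit_utility <- function(tables, p, k, direction = +1) {
  .check_tables(tables); .check_k(tables, k)
  if (tables$strategy != "infomax")
    stop("`tables` is not an infomax table", call. = FALSE)
  if (!direction %in% c(-1, 1))
    stop("`direction` must be +1 or -1", call. = FALSE)
  qv <- .q_at(tables, p, k)
  unname(if (direction > 0) qv["commit_plus"] else qv["commit_minus"])
}

#' @rdname rewardmax_commit_utility
#' @export
infomax_sample_utility <- function(tables, p, k) {
  .check_tables(tables); .check_k(tables, k)
  if (tables$strategy != "infomax")
    stop("`tables` is not an infomax table", call. = FALSE)
  unname(.q_at(tables, p, k)["sample"])
}

#' Interpolated table utility
#'
#' The strategy's value function `U(p; k)` read off the filled table, with
#' linear interpolation between grid knots.
#'
#' @inheritParams rewardmax_commit_utility
#' @return A single utility value.
#' @export
table_utility <- function(tables, p, k) {
  .check_tables(tables); .check_k(tables, k)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  .interp_grid(tables$grid, tables$utility[, as.integer(k) + 1L], p)
}

#' Prescribed action at a belief and time step
#'
#' The argmax action at the interpolated belief among the actions
#' applicable at slot `k` (an action of cost `tau` fits when
#' `k + tau - 1 <= N`; at `k = N` with unit costs the boundary prescribes
#' a commit). Ties follow the documented rules:
#' commit is preferred over sample on exact ties; a commit-direction tie at
#' `p = 0.5` is broken by a fair coin from the current RNG stream (seed it
#' for reproducibility).
#'
#' @inheritParams rewardmax_commit_utility
#' @return One of `"commit_plus"`, `"commit_minus"`, `"sample"`, or
#'   `NA_character_` if no action fits the remaining budget at `k < N`.
#' @examples
#' pars <- task_params(epsilon = 0.05, q = 0.95, N = 5)
#' tab <- build_tables("rewardmax", pars, grid_size = 201)
#' set.seed(1)
#' policy_action(tab, p = 0.5, k = 0)
#' @export
policy_action <- function(tables, p, k) {
  .check_tables(tables); .check_k(tables, k)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  params <- tables$params
  N <- params$N
  feas_c <- (k + params$tau_d - 1) <= N
  feas_s <- (k + params$tau_s - 1) <= N
  qv <- .q_at(tables, p, k)
  sel <- .choose_actions(qv[["commit_plus"]], qv[["commit_minus"]],
                         qv[["sample"]], feas_c, feas_s, p)
  code <- sel$action
  if (is.na(code)) return(NA_character_)
  if (code == 0L) code <- if (runif(1L) < 0.5) 1L else 2L
  c("commit_plus", "commit_minus", "sample")[code]
}

#' @export
print.strategy_tables <- function(x, ...) {
  cat(sprintf("Strategy tables: %s\n", x$strategy))
  cat(sprintf("  belief grid: %d points (%d uniform)\n",
              length(x$grid), x$grid_size))
  cat(sprintf("  time steps: 0..%d\n", x$params$N))
  exploit0 <- mean(x$action[, 1L] != 3L, na.rm = TRUE)
  cat(sprintf("  commit fraction of grid at k = 0: %.3f\n", exploit0))
  invisible(x)
}

#' Tidy export of strategy tables
#'
#' One row per (belief grid point, time step) with the stored utility and
#' action label, suitable for CSV inspection or caching.
#'
#' @param x A `"strategy_tables"` object.
#' @param row.names,optional,... Passed on conventionally (unused).
#' @return A data frame with columns `strategy`, `k`, `p`, `utility`,
#'   `action`.
#' @export
as.data.frame.strategy_tables <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  N <- x$params$N
  G <- length(x$grid)
  data.frame(strategy = x$strategy,
             k = rep(0:N, each = G),
             p = rep(x$grid, N + 1L),
             utility = as.vector(x$utility),
             action = .action_label(as.vector(x$action)))
}
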