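# Explore-exploit phase structure: the closed-form boundary prediction,
# parameter sweeps over (epsilon, q), regime classification, and the
# directional robustness checks of the boundary's parameter dependence.

#' Closed-form explore-exploit boundary
#'
#' The phase transition from occasionally-sampling (explore) to
#' always-committing (exploit) behavior is well approximated by the level
#' set where, at an uninformative belief, feedback from a commitment moves
#' the belief as much on average as one sampled observation:
#' `(1-h) [(1-eps) q + eps (1-q)] = h [eps q + (1-eps)(1-q)]`.
#' Solving for the feedback reliability gives
#' `q* = (h - eps) / (1 - 2 eps)`; above `q*` both strategies prefer pure
#' exploitation. The function returns `NA` where the solution falls
#' outside the physical range `[0.5, 1]` (no boundary crossing) or where
#' `eps = 0.5` degenerates the equation.
#'
#' @param epsilon State-change probability vector in `[0, 0.5)`.
#' @param h Evidence reliability in `(0.5, 1)`.
#' @return Boundary reliability values `q*`, with `NA` where no physical
#'   solution exists. Vectorized over `epsilon`.
#' @examples
#' boundary_reliability(c(0, 0.1, 0.3), h = 0.75)
#' @export
boundary_reliability <- function(epsilon, h) {
  if (any(epsilon < 0 | epsilon > 0.5))
    stop("`epsilon` must lie in [0, 0.5]", call. = FALSE)
  if (h <= 0.5 || h >= 1) stop("`h` must lie in (0.5, 1)", call. = FALSE)
  qs <- ifelse(epsilon == 0.5, NA_real_, (h - epsilon) / (1 - 2 * epsilon))
  ifelse(!is.na(qs) & qs >= 0.5 & qs <= 1, qs, NA_real_)
}

#' Classify a sweep cell's behavioral regime
#'
#' A cell is `"exploit"` when its ensemble contains no sample actions at
#' all, `"boundary"` when the pooled sample/commit burst-length ratio lies
#' in the unity band `[0.5, 2]`, and `"explore"` otherwise.
#'
#' @param ratio Pooled burst-length ratio (sample over commit).
#' @param n_sample Total number of sample actions in the ensemble.
#' @return One of `"exploit"`, `"boundary"`, `"explore"`.
#' @export
classify_regime <- function(ratio, n_sample) {
  if (n_sample == 0L) "exploit"
  else if (ratio >= 0.5 && ratio <= 2) "boundary"
  else "explore"
}

#' Sweep task parameters over environmental stability and reliability
#'
#' For every cell of the `(epsilon, q)` grid, builds both strategies'
#' tables, simulates seeded ensembles, and records burst statistics,
#' regime labels, reward-rate distributions, the normalized reward
#' differential, the robustness differential, and (optionally) action
#' alignment along shared belief trajectories. Both strategies share one
#' derived seed per cell (common random numbers), and the whole sweep is
#' reproducible from `master_seed`.
#'
#' @param epsilon_values,q_values Grid axes (change probability in
#'   `[0, 0.5]`, reliability in `[0.5, 1]`).
#' @param n_realizations Realizations per cell per strategy.
#' @param master_seed Integer master seed.
#' @param base Named list of [task_params()] arguments shared by all cells
#'   (e.g. `gamma`, `h`, `N`, `tau_d`, `tau_s`, `R_correct`,
#'   `R_incorrect`).
#' @param strategies Which strategies to simulate (both by default; the
#'   differentials require both).
#' @param grid_size Belief grid size for [build_tables()].
#' @param alignment If `TRUE`, also run [simulate_aligned_pair()] per cell
#'   and record the alignment fraction.
#' @param driver Driver policy for the alignment trajectories.
#' @return A data frame of class `"sweep_result"`, one row per cell, with
#'   per-strategy columns prefixed `rm_` / `im_`, plus `delta_rho`,
#'   `delta_kappa`, and `alignment`. Attributes `base`, `master_seed`,
#'   `n_realizations`, `epsilon_values`, `q_values` record the setup.
#' @examples
#' sw <- run_sweep(c(0.1, 0.3), c(0.6, 0.9), n_realizations = 20,
#'                 master_seed = 1, grid_size = 201)
#' sw[, c("epsilon", "q", "rm_regime", "im_regime", "delta_rho")]
#' @export
run_sweep <- function(epsilon_values, q_values, n_realizations, master_seed,
                      base = list(), strategies = c("rewardmax", "infomax"),
                      grid_size = 1001L, alignment = FALSE,
                      driver = "rewardmax") {
  strategies <- match.arg(strategies, several.ok = TRUE)
  cells <- expand.grid(epsilon = epsilon_values, q = q_values,
                       KEEP.OUT.ATTRS = FALSE)
  ncell <- nrow(cells)
  seeds <- .derive_seeds(master_seed, 2L * ncell)
  rows <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    pars <- do.call(task_params,
                    c(list(epsilon = cells$epsilon[i], q = cells$q[i]),
                      base))
    row <- list(epsilon = pars$epsilon, q = pars$q, gamma = pars$gamma,
                cell_seed = seeds[i])
    dists <- list()
    for (s in strategies) {
      tab <- build_tables(s, pars, grid_size = grid_size)
      ens <- simulate_ensemble(tab, n_realizations, seeds[i])
      bur <- .pooled_bursts(ens)
      n_sample <- sum(bur$sample_bursts)
      dist <- reward_rate_dist(ens)
      dists[[s]] <- dist
      pre <- if (s == "rewardmax") "rm" else "im"
      row[[paste0(pre, "_ratio")]] <- bur$ratio
      row[[paste0(pre, "_n_sample")]] <- n_sample
      row[[paste0(pre, "_regime")]] <- classify_regime(bur$ratio, n_sample)
      row[[paste0(pre, "_mean_rate")]] <- dist$mean
      row[[paste0(pre, "_std_rate")]] <- dist$std
      row[[paste0(pre, "_kappa")]] <- dist$kappa
      if (s == "rewardmax" && alignment) tab_rm <- tab
      if (s == "infomax" && alignment) tab_im <- tab
    }
    if (length(strategies) == 2L) {
      row$delta_rho <- reward_differential(dists$rewardmax, dists$infomax,
                                           pars$R_correct)
      row$delta_kappa <- robustness_differential(dists$rewardmax,
                                                 dists$infomax)
    } else {
      row$delta_rho <- NA_real_
      row$delta_kappa <- NA_real_
    }
    row$alignment <- if (alignment && length(strategies) == 2L) {
      pairs <- simulate_aligned_pair(tab_rm, tab_im, driver = driver,
                                     n = n_realizations,
                                     master_seed = seeds[ncell + i])
      action_alignment(pairs)
    } else NA_real_
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "base") <- base
  attr(out, "master_seed") <- master_seed
  attr(out, "n_realizations") <- n_realizations
  attr(out, "epsilon_values") <- epsilon_values
  attr(out, "q_values") <- q_values
  attr(out, "driver") <- if (alignment) driver else NA_character_
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Simulated explore-to-exploit transition reliability
#'
#' For each stability value of a sweep, the smallest feedback reliability
#' whose cell is classified as pure exploitation, side by side with the
#' closed-form prediction [boundary_reliability()].
#'
#' @param sweep A `"sweep_result"` from [run_sweep()].
#' @param strategy Which strategy's regime labels to use.
#' @return A data frame with columns `epsilon`, `q_transition` (simulated;
#'   `NA` if no exploit cell in that row), and `q_star` (analytic).
#' @export
transition_reliability <- function(sweep,
                                   strategy = c("rewardmax", "infomax")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(sweep, "sweep_result"))
  col <- if (strategy == "rewardmax") "rm_regime" else "im_regime"
  h <- do.call(task_params,
               c(list(epsilon = sweep$epsilon[1], q = sweep$q[1]),
                 attr(sweep, "base")))$h
  eps_vals <- sort(unique(sweep$epsilon))
  out <- lapply(eps_vals, function(e) {
    rows <- sweep[sweep$epsilon == e, ]
    qx <- sort(rows$q[rows[[col]] == "exploit"])
    data.frame(epsilon = e,
               q_transition = if (length(qx)) qx[1] else NA_real_,
               q_star = boundary_reliability(e, h))
  })
  do.call(rbind, out)
}

# count of exploit-labelled cells for one strategy
.exploit_cells <- function(sweep, strategy) {
  col <- if (strategy == "rewardmax") "rm_regime" else "im_regime"
  sum(sweep[[col]] == "exploit")
}

#' Directional robustness of the phase boundary
#'
#' Verifies, by paired sweeps that differ in exactly one parameter, the
#' qualitative ways the exploitation region must move:
#'
#' 1. a costlier commitment (`tau_d` up) shrinks it;
#' 2. costlier sampling (`tau_s` up) grows it;
#' 3. more reliable evidence (`h` up) shrinks it;
#' 4. a reward larger in magnitude than the punishment expands it for
#'    rewardmax;
#' 5. the infomax regime map is invariant to reward magnitudes;
#' 6. the boundary is insensitive to the budget `N` (exploit-label
#'    disagreements are confined to within one grid step of the analytic
#'    boundary).
#'
#' Checks 1-4 compare exploit-cell counts (non-strict inequalities, since
#' a coarse grid may not move by a full cell); check 5 is an exact
#' cell-by-cell label comparison (same seeds, and reward magnitudes never
#' enter the infomax tables); check 6 allows label flips only in the
#' one-cell band around `q*(epsilon)`.
#'
#' @inheritParams run_sweep
#' @param variants Named list overriding the default perturbations
#'   (`tau_d`, `tau_s`, `h`, `R_correct`, `N`).
#' @return A data frame with one row per check: `check`, `description`,
#'   `pass`, and a human-readable `detail`. Attribute `sweeps` keeps the
#'   underlying sweep results.
#' @export
qualitative_shift_checks <- function(epsilon_values = seq(0.05, 0.45,
                                                          by = 0.1),
                                     q_values = seq(0.55, 0.95, by = 0.1),
                                     n_realizations = 200, master_seed = 1,
                                     base = list(), grid_size = 501L,
                                     variants = list()) {
  v <- modifyList(list(tau_d = 2L, tau_s = 2L, h = 0.85,
                       R_correct = 200, N = 15L), variants)
  sweep_with <- function(over) {
    run_sweep(epsilon_values, q_values, n_realizations, master_seed,
              base = modifyList(base, over), grid_size = grid_size)
  }
  sw_base <- sweep_with(list())
  sw_taud <- sweep_with(list(tau_d = v$tau_d))
  sw_taus <- sweep_with(list(tau_s = v$tau_s))
  sw_h <- sweep_with(list(h = v$h))
  sw_R <- sweep_with(list(R_correct = v$R_correct))
  sw_N <- sweep_with(list(N = v$N))

  counts <- function(sw) c(rm = .exploit_cells(sw, "rewardmax"),
                           im = .exploit_cells(sw, "infomax"))
  c0 <- counts(sw_base)

  res <- list()
  add <- function(check, description, pass, detail) {
    res[[length(res) + 1L]] <<- data.frame(check = check,
                                           description = description,
                                           pass = unname(as.logical(pass)),
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  }

  cd <- counts(sw_taud)
  add("commit_cost_up", "tau_d > tau_s shrinks the exploitation region",
      all(cd <= c0),
      sprintf("exploit cells rm %d->%d, im %d->%d",
              c0["rm"], cd["rm"], c0["im"], cd["im"]))
  cs <- counts(sw_taus)
  add("sample_cost_up", "tau_s > tau_d grows the exploitation region",
      all(cs >= c0),
      sprintf("exploit cells rm %d->%d, im %d->%d",
              c0["rm"], cs["rm"], c0["im"], cs["im"]))
  ch <- counts(sw_h)
  add("evidence_up", "larger h shrinks the exploitation region",
      all(ch <= c0),
      sprintf("exploit cells rm %d->%d, im %d->%d",
              c0["rm"], ch["rm"], c0["im"], ch["im"]))
  cR <- counts(sw_R)
  add("reward_asymmetry_rm",
      "|R_correct| > |R_incorrect| expands rewardmax exploitation",
      cR["rm"] >= c0["rm"],
      sprintf("rm exploit cells %d->%d", c0["rm"], cR["rm"]))
  add("reward_invariance_im",
      "infomax regime map is invariant to reward magnitudes",
      identical(sw_R$im_regime, sw_base$im_regime),
      sprintf("%d/%d cells identical",
              sum(sw_R$im_regime == sw_base$im_regime), nrow(sw_base)))
  h_base <- do.call(task_params,
                    c(list(epsilon = 0.1, q = 0.8), base))$h
  dq <- max(diff(sort(unique(q_values))))
  qstar <- boundary_reliability(pmin(sw_base$epsilon, 0.5), h_base)
  near <- !is.na(qstar) & abs(sw_base$q - qstar) <= dq + 1e-9
  flips <- (sw_N$rm_regime == "exploit") != (sw_base$rm_regime == "exploit") |
    (sw_N$im_regime == "exploit") != (sw_base$im_regime == "exploit")
  add("budget_insensitivity",
      "exploit map under a different N differs only near the boundary",
      all(!flips | near),
      sprintf("%d flipped cells, %d outside the boundary band",
              sum(flips), sum(flips & !near)))

  out <- do.call(rbind, res)
  attr(out, "sweeps") <- list(base = sw_base, tau_d = sw_taud,
                              tau_s = sw_taus, h = sw_h, R = sw_R, N = sw_N)
  out
}

#' Heat-map display of a sweep metric
#'
#' Base-graphics image of one sweep column over the `(epsilon, q)` grid.
#'
#' @param x A `"sweep_result"`.
#' @param metric Column to display (default the burst ratio of rewardmax).
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.sweep_result <- function(x, metric = "rm_ratio", ...) {
  eps <- sort(unique(x$epsilon)); qs <- sort(unique(x$q))
  z <- matrix(NA_real_, length(eps), length(qs))
  for (i in seq_along(eps)) for (j in seq_along(qs)) {
    v <- x[[metric]][x$epsilon == eps[i] & x$q == qs[j]]
    z[i, j] <- if (length(v)) v[1] else NA_real_
  }
  graphics::image(eps, qs, z, xlab = "state-change probability (epsilon)",
                  ylab = "feedback reliability (q)", main = metric, ...)
  invisible(x)
}

#' Write a sweep to CSV with a JSON manifest
#'
#' The cell-level table goes to `<path>.csv`; the manifest (`<path>.json`)
#' records the grid, master seed, base parameters, and package version for
#' provenance.
#'
#' @param sweep A `"sweep_result"`.
#' @param path Output path stem (without extension).
#' @return The CSV path, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  csv <- paste0(path, ".csv")
  write.csv(as.data.frame(sweep), csv, row.names = FALSE)
  manifest <- list(
    epsilon_values = attr(sweep, "epsilon_values"),
    q_values = attr(sweep, "q_values"),
    n_realizations = attr(sweep, "n_realizations"),
    master_seed = attr(sweep, "master_seed"),
    base = attr(sweep, "base"),
    package_version = as.character(packageVersion("foragedp")))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(csv)
}
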