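pars_mid <- task_params(epsilon = 0.1, q = 0.8)

test_that("unit-cost episodes spend the whole budget on exactly N actions", {
  tab <- cached_tables("rewardmax", pars_mid)
  for (seed in c(1, 2, 3, 50)) {
    sim <- simulate_realization(tab, seed)
    ev <- sim$events
    expect_identical(nrow(ev), 10L)
    expect_identical(ev$k, 1:10)          # slots strictly increasing by 1
    expect_equal(sim$total_reward, sum(ev$reward))
    # rewards attach to feedback, and only to commits
    commits <- ev$action != "sample"
    expect_true(all(ev$reward[!commits] == 0))
    expect_equal(ev$reward[commits],
                 ifelse(ev$feedback[commits] == "reward", 100, -100))
  }
})

test_that("time costs are conserved against the budget", {
  pars <- task_params(0.1, 0.8, tau_d = 3, tau_s = 2)
  tab_rm <- build_tables("rewardmax", pars, grid_size = 301)
  for (seed in 1:5) {
    ev <- simulate_realization(tab_rm, seed)$events
    costs <- ifelse(ev$action == "sample", pars$tau_s, pars$tau_d)
    expect_lte(sum(costs), pars$N)
    # each slot advances by the acting action's cost
    expect_equal(diff(ev$k), costs[-length(costs)])
    # no further action would have fit after the last one completed
    k_next <- ev$k[length(ev$k)] + costs[length(costs)]
    expect_gt(k_next + min(pars$tau_d, pars$tau_s) - 1, pars$N)
  }
})

test_that("a fixed seed reproduces the realization exactly", {
  tab <- cached_tables("rewardmax", pars_mid)
  a <- simulate_realization(tab, 99)
  b <- simulate_realization(tab, 99)
  expect_identical(a, b)
})

test_that("replaying the event log through the belief updates matches", {
  for (s in c("rewardmax", "infomax")) {
    tab <- cached_tables(s, pars_mid)
    for (seed in c(4, 11, 23)) {
      sim <- simulate_realization(tab, seed)
      expect_equal(replay_llr(sim), sim$events$llr_after,
                   tolerance = 1e-12)
    }
  }
})

test_that("an ensemble is seed-derived and its first member is a plain realization", {
  tab <- cached_tables("rewardmax", pars_mid)
  ens <- simulate_ensemble(tab, 5, master_seed = 31)
  ens2 <- simulate_ensemble(tab, 5, master_seed = 31)
  expect_identical(ens, ens2)
  expect_identical(ens[[1]],
                   simulate_realization(tab, ens[[1]]$seed))
  expect_identical(length(simulate_ensemble(tab, 1, 31)), 1L)
})

test_that("empirical feedback accuracy matches q given decision correctness", {
  tab <- cached_tables("rewardmax", pars_mid)
  ens <- simulate_ensemble(tab, 400, master_seed = 8)
  agree <- unlist(lapply(ens, function(r) {
    ev <- r$events[r$events$action != "sample", ]
    d <- ifelse(ev$action == "commit_plus", 1, -1)
    (ev$feedback == "reward") == (d == ev$state)
  }))
  n <- length(agree)
  expect_lt(abs(mean(agree) - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("a deterministic world locks in after the first commit", {
  # eps = 0, q = 1: feedback fully reveals the (never-changing) state
  pars <- task_params(0, 1, h = 0.75)
  tab <- build_tables("rewardmax", pars, grid_size = 301)
  for (seed in 1:10) {
    ev <- simulate_realization(tab, seed)$events
    commits <- which(ev$action != "sample")
    expect_gt(length(commits), 1)
    after_first <- commits[-1]
    expect_true(all(ev$feedback[after_first] == "reward"))
    expect_identical(unique(ev$action[after_first]),
                     ev$action[commits[2]])
  }
})

test_that("the exploit regime never samples", {
  pars <- task_params(0.05, 0.95)
  tab <- cached_tables("rewardmax", pars)
  ens <- simulate_ensemble(tab, 100, master_seed = 5)
  acts <- unlist(lapply(ens, function(r) r$events$action))
  expect_false(any(acts == "sample"))
})

test_that("parameter mismatches are configuration errors", {
  tab <- cached_tables("rewardmax", pars_mid)
  other <- task_params(0.2, 0.8)
  expect_error(simulate_realization(tab, 1, params = other),
               "does not match")
  tab_im <- cached_tables("infomax", pars_mid)
  tab_im_other <- build_tables("infomax", other, grid_size = 301)
  expect_error(simulate_aligned_pair(tab, tab_im_other, n = 1,
                                     master_seed = 1),
               "different task parameters")
  expect_error(simulate_aligned_pair(tab_im, tab, n = 1, master_seed = 1),
               "in that order")
})

test_that("aligned pairs agree step-for-step in the exploit corner", {
  pars <- task_params(0.05, 0.95)
  tab_rm <- cached_tables("rewardmax", pars)
  tab_im <- cached_tables("infomax", pars)
  for (drv in c("rewardmax", "infomax")) {
    pairs <- simulate_aligned_pair(tab_rm, tab_im, driver = drv,
                                   n = 50, master_seed = 13)
    expect_gte(action_alignment(pairs), 0.95)
    expect_identical(attr(pairs, "driver"), drv)
    expect_true(all(pairs$k >= 1 & pairs$k <= pars$N))
  }
})

test_that("realization events export to CSV with provenance stamps", {
  tab <- cached_tables("rewardmax", pars_mid)
  sim <- simulate_realization(tab, 3)
  f <- tempfile(fileext = ".csv")
  write_realization_csv(sim, f)
  got <- read.csv(f)
  expect_identical(nrow(got), nrow(sim$events))
  expect_true(all(c("seed", "strategy", "params_key") %in% names(got)))
  unlink(f)
})
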