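pars_default <- task_params(epsilon = 0.1, q = 0.8)

test_that("binary entropy has the right landmarks", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.75), -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_error(binary_entropy(1.2), "must lie")
  expect_error(binary_entropy(-0.2), "must lie")
})

test_that("terminal commit expectation matches outcome enumeration", {
  p1 <- task_params(0.1, q = 1)
  expect_equal(rewardmax_terminal_utility(1, p1), 100)
  expect_equal(rewardmax_terminal_utility(0.5, pars_default), 0)
  p8 <- task_params(0.1, q = 0.8)
  # 0.9 * 60 + 0.1 * (-60)
  expect_equal(rewardmax_terminal_utility(0.9, p8), 48)
  # symmetric under relabeling of the states
  p <- seq(0, 1, by = 0.01)
  expect_equal(rewardmax_terminal_utility(p, p8),
               rewardmax_terminal_utility(1 - p, p8))
})

test_that("greedy (gamma = 0) commit utility collapses to the one-shot expectation", {
  pars <- task_params(0.15, 0.85, N = 4, gamma = 0)
  knots <- c(0.2, 0.5, 0.7, 0.9)
  tab <- cached_tables("rewardmax", pars, grid_size = 501,
                       extra_knots = knots)
  for (p in knots) {
    pr <- 0.85 * p + 0.15 * (1 - p)
    one_shot <- pr * 100 + (1 - pr) * (-100)
    for (k in 0:3)
      expect_equal(rewardmax_commit_utility(tab, p, k, +1), one_shot)
    # and sampling gains nothing without a future
    expect_equal(rewardmax_sample_utility(tab, p, 1), 0)
  }
  # greedy rewardmax prescribes commit everywhere
  expect_false(any(tab$action == 3L, na.rm = TRUE))
})

test_that("commit utilities are direction-symmetric at the neutral belief", {
  tab <- cached_tables("rewardmax", pars_default)
  for (k in c(0, 3, 7, 10))
    expect_equal(rewardmax_commit_utility(tab, 0.5, k, +1),
                 rewardmax_commit_utility(tab, 0.5, k, -1),
                 tolerance = 1e-10)
})

test_that("infomax immediate gains vanish when information cannot flow", {
  # uninformative feedback: q = 0.5, greedy horizon
  pars_q <- task_params(0.1, 0.5, gamma = 0)
  tab_q <- cached_tables("infomax", pars_q, grid_size = 501,
                         extra_knots = c(0.3, 0.8))
  expect_equal(infomax_commit_utility(tab_q, 0.8, 2, +1), 0,
               tolerance = 1e-12)
  # unpredictable next state: eps = 0.5
  pars_e <- task_params(0.5, 0.9, gamma = 0)
  tab_e <- cached_tables("infomax", pars_e, grid_size = 501,
                         extra_knots = c(0.3, 0.8))
  expect_equal(infomax_commit_utility(tab_e, 0.3, 2, +1), 0,
               tolerance = 1e-12)
  # sampling from certainty teaches nothing
  expect_equal(infomax_sample_utility(tab_q, 1, 2), 0, tolerance = 1e-12)
})

test_that("infomax sampling gain at a neutral belief is 1 - H(h)", {
  pars <- task_params(0.1, 0.8, gamma = 0)
  tab <- cached_tables("infomax", pars, grid_size = 501,
                       extra_knots = c(0.5))
  expect_equal(infomax_sample_utility(tab, 0.5, 2),
               1 - binary_entropy(0.75), tolerance = 1e-12)
  # near-uninformative evidence yields a near-zero gain
  pars_h <- task_params(0.1, 0.8, h = 0.5001, gamma = 0)
  tab_h <- build_tables("infomax", pars_h, grid_size = 201,
                        extra_knots = 0.5)
  expect_lt(infomax_sample_utility(tab_h, 0.5, 2), 1e-6)
})

test_that("infomax is indifferent to the commit direction", {
  # feedback is informative about the state whichever option is chosen
  tab <- cached_tables("infomax", pars_default)
  for (p in c(0.2, 0.5, 0.9))
    for (k in c(0, 4, 9))
      expect_equal(infomax_commit_utility(tab, p, k, +1),
                   infomax_commit_utility(tab, p, k, -1),
                   tolerance = 1e-12)
})

test_that("stored utilities are the max of the applicable action utilities", {
  for (s in c("rewardmax", "infomax")) {
    tab <- cached_tables(s, pars_default)
    N <- pars_default$N
    for (k in c(0, 2, 5, 9)) {
      col <- k + 1L
      best <- pmax(tab$Q$commit_plus[, col], tab$Q$commit_minus[, col],
                   tab$Q$sample[, col])
      expect_equal(tab$utility[, col], best, tolerance = 1e-12)
    }
    # terminal boundary
    if (s == "rewardmax")
      expect_equal(tab$utility[, N + 1L],
                   rewardmax_terminal_utility(tab$grid, pars_default))
    else
      expect_equal(tab$utility[, N + 1L], rep(0, length(tab$grid)))
    # never sample at the boundary
    expect_false(any(tab$action[, N + 1L] == 3L, na.rm = TRUE))
  }
})

test_that("small-budget tables equal exhaustive expectimax enumeration", {
  cfgs <- list(task_params(0.1, 0.8, N = 2),
               task_params(0.2, 0.7, N = 3, gamma = 0.5))
  for (pars in cfgs) {
    pairs <- reachable_pairs(pars)
    knots <- sort(unique(pairs$p))
    for (s in c("rewardmax", "infomax")) {
      tab <- build_tables(s, pars, grid_size = 301, extra_knots = knots)
      for (i in seq_len(nrow(pairs)))
        expect_equal(table_utility(tab, pairs$p[i], pairs$k[i]),
                     oracle_value(s, pairs$p[i], pairs$k[i], pars),
                     tolerance = 1e-8)
    }
  }
})

test_that("tables are symmetric under relabeling the states", {
  for (s in c("rewardmax", "infomax")) {
    tab <- cached_tables(s, pars_default)
    G <- length(tab$grid)
    rev_idx <- G:1
    expect_equal(tab$utility, tab$utility[rev_idx, ], tolerance = 1e-9)
    # actions mirror with commit_plus <-> commit_minus away from ties
    a <- tab$action
    a_mirror <- a[rev_idx, ]
    swapped <- a_mirror
    swapped[a_mirror == 1L] <- 2L
    swapped[a_mirror == 2L] <- 1L
    ok <- a == swapped | a == 0L | a_mirror == 0L
    expect_gt(mean(ok, na.rm = TRUE), 0.999)
  }
})

test_that("doubling the belief grid leaves utilities stable", {
  for (s in c("rewardmax", "infomax")) {
    t1 <- cached_tables(s, pars_default, grid_size = 1001)
    t2 <- cached_tables(s, pars_default, grid_size = 2001)
    u1 <- t1$utility[, 1]
    u2 <- t2$utility[seq(1, 2001, by = 2), 1]
    rel <- abs(u1 - u2) / (1 + abs(u2))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("the policy commits everywhere in the exploit regime", {
  pars <- task_params(0.05, 0.95)
  tab <- cached_tables("rewardmax", pars)
  set.seed(1)
  for (k in 0:10)
    expect_match(policy_action(tab, 0.5, k), "^commit")
  # biased beliefs commit toward the likelier state
  expect_identical(policy_action(tab, 0.9, 3), "commit_plus")
  expect_identical(policy_action(tab, 0.1, 3), "commit_minus")
})

test_that("an exact direction tie at p = 0.5 is broken by a fair coin", {
  pars <- task_params(0.05, 0.95)
  tab <- cached_tables("rewardmax", pars)
  set.seed(123)
  draws <- replicate(200, policy_action(tab, 0.5, 0))
  expect_setequal(unique(draws), c("commit_plus", "commit_minus"))
  expect_error(policy_action(tab, 0.5, 11), "time step")
  expect_error(policy_action(tab, 1.5, 0), "must lie")
})

test_that("tables round-trip to a tidy data frame", {
  pars <- task_params(0.1, 0.8, N = 3)
  tab <- build_tables("rewardmax", pars, grid_size = 11)
  df <- as.data.frame(tab)
  expect_identical(nrow(df), 11L * 4L)
  expect_named(df, c("strategy", "k", "p", "utility", "action"))
  expect_true(all(df$action %in%
                    c("commit_plus", "commit_minus", "sample",
                      "commit_either")))
})
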