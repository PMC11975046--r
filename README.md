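# foragedp

Normative reward- and information-seeking decision strategies for a
sequential, dynamic two-alternative foraging task, built and compared by
belief-state dynamic programming and seeded Monte-Carlo simulation.

## The problem

A forager faces a world that sits in one of two hidden states (which of
two patches is productive, say) and can, at each step of a fixed budget of
`N` time steps, either **sample** one more noisy observation of the
current state or **commit** to a choice. Committing yields probabilistic
feedback — reward `R+` or punishment `R-` that matches the correctness of
the choice with reliability `q` — and afterwards the state flips with
probability `ε`. Observations point at the true state with probability
`h`. A Bayes-optimal agent carries its belief as the log-likelihood ratio

```
y = ln Pr(s+ | data) / Pr(s- | data),      p = 1 / (1 + e^(-y)),
```

adding `±ln(h/(1-h))` per observation and conditioning exactly on
(decision, feedback, possible state change) across commitments.

The package implements two normative policies over this common belief by
finite-horizon backward induction (Bellman recursion on a discretized
belief space):

* **rewardmax** — maximizes expected total reward over the budget
  (equivalently the reward rate `ρ = ⟨R⟩/N`);
* **infomax** — maximizes expected cumulative reduction of the state
  entropy `H(p)`, a budgeted sequential generalization of infotaxis, with
  feedback information normalized against the uninformative-feedback
  (`q = 0.5`) baseline.

On top of the policies it provides: episode simulation with full event
logs; commit/sample **burst statistics**; **action alignment** between
the two strategies along shared belief trajectories; empirical
**reward-rate distributions**, the normalized differential
`Δρ = 100(ρ_rm − ρ_im)/R+`, and the **robustness** index
`κ = ⟨ρ̃⟩/std(ρ̃)` with `Δκ = κ_rm − κ_im`; the closed-form
explore–exploit phase boundary `q*(ε) = (h − ε)/(1 − 2ε)`; and parameter
sweeps over `(ε, q)` with regime classification and directional
boundary-shift checks.

For whom: computational neuroscientists and behavioral ecologists who
want a reproducible testbed for comparing reward-seeking and
information-seeking accounts of explore–exploit behavior in volatile
environments.

## Worked example

One volatile, reliable-feedback cell (`ε = 0.25`, `q = 0.9`), both
strategies, 1000 seeded episodes each:

```r
library(foragedp)
pars <- task_params(epsilon = 0.25, q = 0.9)   # h = 0.75, N = 10, R = (100, -100)
tab_rm <- build_tables("rewardmax", pars)
tab_im <- build_tables("infomax", pars)

sim <- simulate_realization(tab_im, seed = 7)
sim$events[, c("k", "state", "action", "observation", "feedback", "reward")]
#>     k state       action observation   feedback reward
#> 1   1    -1       sample          -1       <NA>      0
#> 2   2    -1       sample          -1       <NA>      0
#> 3   3    -1 commit_minus          NA     reward    100
#> 4   4    -1       sample          -1       <NA>      0
#> 5   5    -1 commit_minus          NA     reward    100
#> 6   6    -1       sample          -1       <NA>      0
#> 7   7    -1 commit_minus          NA     reward    100
#> 8   8     1       sample           1       <NA>      0
#> 9   9     1       sample           1       <NA>      0
#> 10  10    1  commit_plus          NA punishment   -100

extract_bursts(sim$events$action)
#> Burst statistics
#>   commit bursts: 1, 1, 1, 1
#>   sample bursts: 2, 1, 1, 2
#>   mean commit 1, mean sample 1.5, ratio 1.5
```

The infomax agent interleaves sampling with commitments (burst ratio 1.5:
exploratory); the budget of 10 steps is spent on exactly 10 unit-cost
actions; the state flipped once (between slots 7 and 8) and the agent's
final commit was caught out by it.

```r
d_rm <- reward_rate_dist(simulate_ensemble(tab_rm, 1000, master_seed = 42))
d_im <- reward_rate_dist(simulate_ensemble(tab_im, 1000, master_seed = 42))
d_rm
#> Reward-rate distribution: n = 1000, mean 28.7, sd 29.71, kappa 0.966
d_im
#> Reward-rate distribution: n = 1000, mean 16.62, sd 15.64, kappa 1.063
reward_differential(d_rm, d_im, 100)      # 12.08
robustness_differential(d_rm, d_im)       # -0.0967
boundary_reliability(0.25, 0.75)          # 1: no exploit transition at this volatility
```

This is the package's central comparison in one cell: the reward-seeker earns more
on average (`Δρ ≈ +12%` of a correct response) but with twice the spread;
the information-seeker's returns are steadier (`Δκ < 0`, higher
robustness). `run_sweep()` repeats this over an `(ε, q)` grid and labels
each cell's regime; `qualitative_shift_checks()` verifies how the
exploitation region must move as costs, evidence quality, and reward
asymmetry change.

A thin command-line front end over these functions ships in
`inst/cli/foragedp.R` (subcommands `tables`, `simulate`, `sweep`,
`boundary`, `align`, `check`; configuration via a YAML file, see
`run_config()`).

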