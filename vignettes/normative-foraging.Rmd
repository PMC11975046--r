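---
title: "Normative reward- and information-seeking strategies for dynamic foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative reward- and information-seeking strategies for dynamic foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and its model

`foragedp` studies a sequential two-alternative foraging problem. Between
decisions the environment sits in one of two hidden states, `s+` or `s-`
(say, which of two patches is the productive one). The agent repeatedly
chooses between two kinds of action:

* **sample** — draw one more observation of the current state. Observations
  are signed units, pointing at the true state with probability `h`
  (Bernoulli evidence; `h = 0.75` by default).
* **commit** — declare a decision for `s+` or `s-`. Commitment triggers
  probabilistic feedback: with probability `q` (the feedback reliability)
  the reward/punishment sign matches the correctness of the decision.
  `R_correct` is delivered on positive feedback and `R_incorrect` on
  negative feedback, whatever the underlying truth. After feedback, the
  environment flips state with probability `epsilon` (the volatility or,
  inversely, stability of the world), and the next trial begins.

Actions cost time: `tau_s` steps per observation, `tau_d` per commitment,
out of a fixed budget of `N` steps. All task constants live in one
validated object:

```{r}
library(foragedp)
pars <- task_params(epsilon = 0.1, q = 0.8)   # h = 0.75, N = 10, etc.
pars
```

### Belief updating

A Bayes-optimal agent summarizes everything it has seen in the
log-likelihood ratio (LLR) `y = ln Pr(s+)/Pr(s-)`, equivalently the state
likelihood `p = 1/(1 + exp(-y))`. Within a trial each observation adds
`±ln(h/(1-h))` to the LLR (`update_belief()`). Across a commitment the
belief is carried over by exact Bayesian conditioning on the decision and
its feedback, marginalizing over the possible current states and the
flip process (`prior_after_decision()`). We implement the exact
law-of-total-probability form, which coincides with the familiar
two-branch closed form (with its `sign(d)` prefactor and `|y|`) whenever
the decision agrees in sign with the belief — the only case a normative
policy produces — and remains correct for off-policy decisions too. The
test suite checks it against an explicit enumeration over (current state,
next state, feedback) to `1e-10`.

The LLR is the canonical stored quantity and is clamped to `±50`;
likelihoods are derived on demand. At the clamp `p` is numerically
indistinguishable from 0/1, and the one undefined corner — conditioning on
a probability-zero feedback branch under `q = 1` — falls back to the
uninformative prior.

## The two objectives

Both strategies use the same beliefs and differ only in the utility that
backward induction maximizes.

**rewardmax** maximizes expected total reward over the budget (the reward
rate, since the horizon is fixed at `N`). The utility of a commit is its
expected immediate reward plus the discounted table value at the
carried-over belief; the utility of sampling is the discounted expectation
of the table value over the two-point predictive distribution of the next
likelihood.

**infomax** maximizes the expected cumulative reduction of state entropy
`H(p)` (in bits), a budgeted, sequential generalization of infotaxis. A
sample is worth `H(p) - E[H(p')]` plus the discounted continuation. A
commit is worth the entropy of the *baseline* next-state marginal
`p + epsilon - 2 p epsilon` (what the agent would know about the next
state if feedback were uninformative, `q = 0.5`) minus the
feedback-weighted entropies of the carried-over beliefs, plus discounted
continuations. Without this baseline the persistence of the environment
itself would be miscounted as feedback information. One consequence worth
knowing: the infomax commit utility is exactly direction-symmetric —
feedback is equally informative whichever option is chosen — so its
commit direction is resolved toward the more likely state.

The discount `gamma` multiplies the continuation utility once per action,
exactly as the recursions are written — not once per elapsed time step.
With equal unit costs the distinction is invisible; with `tau_d != tau_s`
it matters, and this is the documented convention. At `gamma = 0` both
agents become greedy: rewardmax commits everywhere, infomax reduces to
classic next-step infotaxis.

### Time indexing and the terminal rule

Utility tables are matrices over (belief grid) x (action slot `0..N`). An
action at slot `k` occupies time steps `k..k+tau-1` and is applicable when
`k + tau - 1 <= N`; an episode occupies slots `1..N`, which under unit
costs is exactly `N` actions. The terminal column `N` is the boundary
value: for rewardmax the one-shot commit expectation (with no future, one
more observation is worthless), for infomax identically zero (no further
information gain is possible), and it prescribes a commit. Continuations
indexed past `N` are truncated to zero. With mixed costs the terminal
column can describe a commit that no longer fits the budget; the simulator
never initiates such an action (feasibility is checked against the
remaining budget), so the approximation only touches valuations within
one action of the horizon.

### Discretization and ties

Backward induction runs on a uniform likelihood grid (1001 points by
default) with linear interpolation for off-grid lookups. Interpolating in
`p` rather than LLR keeps the two-point sampling transition and both
utility definitions in their native coordinates. The grid is validated two
ways: doubling its size changes utilities by less than `1e-3` (relative),
and for small budgets the induction is run with every reachable belief
inserted as a knot (`reachable_beliefs()`), where it must — and does —
agree with exhaustive expectimax enumeration to better than `1e-8`.

Ties are resolved by fixed rules: commit beats sample on a
(numerically) exact tie, since commitment also yields feedback
information; a commit-direction tie away from `p = 0.5` follows the
belief; the genuinely symmetric tie at exactly `p = 0.5` is broken by a
fair coin from the seeded stream so ensemble statistics stay symmetric.

## Simulation: what the generator emulates

`simulate_realization()` plays one seeded episode: uniform initial hidden
state, uninformative initial belief, then alternating policy queries and
environment responses until no action fits the remaining budget. The
event log records, per action, the slot, hidden state, action,
observation or feedback, belief before/after, and delivered reward; the
suite verifies that replaying the log through the belief updates
reproduces every recorded belief.

Randomness follows R convention with explicit seeding at every entry
point: a master seed fans out to per-realization (or per-sweep-cell)
seeds via `sample.int`, so each realization is reproducible on its own
and ensembles are order-independent. Inside a sweep the two strategies
share each cell's seed (common random numbers), which makes the
strategies' ensembles *identical* wherever their policies coincide (pure
exploitation) — differentials there are exactly zero rather than noisy.

The generator emulates exactly the stylized task: binary states,
i.i.d. Bernoulli evidence, state changes only at commitments, feedback
delivered instantly. It does not emulate within-trial volatility,
more than two alternatives, non-Bernoulli evidence, sensory or motor
delays, or learning of the task parameters — so passing tests speak to
the normative model itself, not to fits of animal behavior.

## Metrics

* **Burst statistics** (`extract_bursts()`): maximal runs of same-category
  actions. The summary ratio (mean sample-burst length over mean
  commit-burst length) is 0 for pure exploitation, infinite if the agent
  never commits; sweep cells pool bursts across the ensemble (a
  per-realization variant is trivial to compute from the same lists).
* **Action alignment** (`simulate_aligned_pair()`, `action_alignment()`):
  both policies queried with identical beliefs and remaining budget along
  shared trajectories; the fraction of identical prescriptions. The
  metric's definition leaves the trajectory's generator open;
  here the rewardmax policy drives by default, a `driver` switch allows
  the infomax policy to drive, and the suite checks the conclusions are
  driver-robust. Direction ties at `p = 0.5` consume one shared coin per
  step so exact indifference cannot masquerade as disagreement.
* **Reward-rate distributions** (`reward_rate_dist()`): one empirical rate
  (total reward / `N`) per realization. The robustness index
  `kappa = mean/sd` uses the population standard deviation — the ensemble
  is the full object of study, not a sample — with an infinite sentinel
  for zero spread. `reward_differential()` reports
  `100 (rho_rm - rho_im) / R_correct`, the rewardmax advantage as a
  percentage of one correct-response reward.

## Phase structure

Where feedback moves a neutral belief more than a single observation
does, sampling loses its purpose and both strategies switch to pure
exploitation. Equating the two mean belief increments at `y = 0` gives
the level set `(1-h)[(1-eps) q + eps(1-q)] = h[eps q + (1-eps)(1-q)]`,
solved in closed form by

```
q*(eps) = (h - eps) / (1 - 2 eps),
```

returned by `boundary_reliability()` (with `NA` where the solution leaves
`[0.5, 1]`). `run_sweep()` classifies each `(epsilon, q)` cell as
`exploit` (no sample action in the whole ensemble), `boundary` (pooled
burst ratio inside the unity band `[0.5, 2]` — the band half-width is this
package's documented choice), or `explore`. The simulated rewardmax
transition tracks `q*` to within one grid cell on the default sweep; the
infomax transition is visibly less sharp and sits one to two cells above
it at high stability, consistent with its softer preference structure.
`qualitative_shift_checks()` verifies the six directional ways the
exploitation region must move (time costs, evidence reliability, reward
asymmetry for rewardmax only, reward invariance of infomax, budget
insensitivity).

## Problem sizes and numerical choices

The reference parameter set is `h = 0.75`, `N = 10`, `tau_d = tau_s = 1`,
rewards `(100, -100)`, `gamma = 1`, with `epsilon` and `q` swept. The
package defaults to desk-scale ensembles: sweeps of 9 x 9 cells at
500-2000 realizations per cell per strategy (raise to 1e4 for
presentation-quality maps).
Specifically, the robustness comparison uses 2000 realizations/cell
because the sign of a near-zero `delta kappa` is the statistic of
interest and flips under coarser Monte-Carlo noise, while mean reward
differentials are stable already at 500. The reward-differential maximum
is scanned across discounting levels `gamma = 1, 0.5, 0`, the condition
set of the differential maps; its peak arises under strong
discounting, where the greedy reward-seeker stops sampling entirely while
the information-seeker keeps exploring. The acceptance suite asserts the
qualitative claims (boundary tracking, robustness ordering, alignment
structure, directional shifts) and the quantitative peak differential at
these sizes.

## Known limitations

* The explore-exploit boundary formula is an approximation derived at the
  neutral belief; it is asserted only against the rewardmax transition and
  only to one-grid-cell accuracy.
* Discounting per action (not per time step) and the terminal-column
  convention follow the recursions exactly as written above, but they are
  genuine modeling choices when `tau_d != tau_s`.
* Utilities between grid knots are linear interpolants; exactness holds at
  knots (and thus at all reachable beliefs for small budgets), not
  between them.
* No inference machinery is provided: the package simulates and compares
  normative policies, it does not fit them to data.
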