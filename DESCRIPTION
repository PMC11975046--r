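Package: foragedp
Title: Normative Reward- and Information-Seeking Strategies for Dynamic Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Belief-state dynamic programming for a sequential two-alternative
    foraging task in a changing environment. Implements Bayesian log-likelihood
    ratio belief updating within and across trials, finite-horizon backward
    induction for a reward-maximizing ("rewardmax") and an
    information-maximizing ("infomax") agent, seeded Monte-Carlo simulation of
    agent-environment episodes, behavioral metrics (commit/sample burst
    statistics, action alignment, empirical reward-rate distributions,
    robustness), a closed-form explore-exploit phase boundary, and parameter
    sweeps over environmental stability and feedback reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
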