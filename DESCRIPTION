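Package: seqreach
Title: Simulation and Analysis of Sequential Reaching Kinematics Under
    Reward and Dopaminergic Manipulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying motor vigour and movement fusion in
    sequential reaching tasks. Provides a synthetic cohort generator for
    two-dimensional cursor trajectories through a via-point target layout,
    kinematic measurement (movement time, per-segment peak velocity,
    per-transition fusion index from Gaussian-smoothed speed profiles), a
    closed-loop rank-percentile reward engine, experiment scheduling and
    trial-exclusion rules, and the statistical inference stack used for
    such designs: linear mixed models with marginal trial slopes and
    pairwise z-tests, row-shuffle permutation tests for significant trial
    windows, median-based mixed ANOVAs with Wilcoxon follow-ups, and a
    probabilistic Go/NoGo positive control with a working-memory median
    split.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
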