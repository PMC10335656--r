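Package: takeoverlearn
Title: Decoding Anticipatory EEG Potentials and Learning Human-Robot Task
    Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how a robot can learn a human partner's
    preferred subtask assignment from single-trial decoding of anticipatory
    brain potentials. Provides a synthetic generator for labelled EEG epochs
    with a controllable event-related component on 1/f background noise; a
    single-trial decoding pipeline (windowed time-domain features,
    shrinkage-regularized linear discriminant analysis, class-balanced
    repeated cross-validation, and a sample-size adjusted binomial chance
    level); a stochastic model of an imperfect anticipation decoder driven by
    per-context true-negative/true-positive rates; a bandit-style
    reinforcement learner with per-trial memory standardization and a softmax
    policy; and a simulation harness that produces repetition-averaged
    learning curves for task sizes, decoder-quality sweeps, dynamic
    re-assignment, and imbalanced assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
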