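Package: delaycredit
Title: Simulation and Analysis of a State-Transition-Free Delayed-Feedback
    Learning Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying temporal credit assignment under delayed,
    unpredictably timed feedback. Implements a two-choice task in which one
    stimulus pair yields immediate reward, a second pair yields a reward
    delivered only at a later trial of a third pair, and trial types are
    interleaved in randomized units so that state transitions carry no
    information about outcomes. Provides quasi-random sequence generation
    with a bounded FIFO queue of pending delayed rewards, actor-critic and
    Q-learning agents with softmax choice and eligibility traces, a
    synthetic-participant cohort generator with labelled behavioral
    archetypes, per-participant bias statistics (exponentially weighted
    choice rates, learning-criterion detection, binomial, chi-square and
    Fisher exact tests) assembled into a six-criterion classification
    table, and a simulation grid producing final-bin choice histograms
    and choice-rate scatter summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
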