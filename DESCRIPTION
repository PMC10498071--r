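Package: msart
Title: Simulation and Scoring Toolkit for an Adaptive Go/No-Go Sustained
    Attention Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Headless, seedable simulator for a modified Sustained Attention
    to Response Task (mSART) in which the no-go stimulus probability adapts
    over nine difficulty modes as a function of consecutive commission
    errors, together with a scoring layer for mind-wandering measures
    (error rates, pre-no-go mean reaction time and its coefficient of
    variation, signal-detection d-prime, deepest mode reached and the
    mild/moderate/severe classification, 5-minute time-window summaries)
    and the matching inferential layer (one-way and Welch ANOVA with
    partial eta squared, Scheirer-Ray-Hare rank-based two-way test,
    Tukey/Games-Howell/Bonferroni post hoc comparisons, and a-priori
    sample-size computation from the noncentral F distribution). Synthetic
    responders with a two-state Markov attention process generate the
    behavioral signatures of mind-wandering without human data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
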