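Package: seqsurprise
Title: Bayesian Ideal Observers for Binary Sequence Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ideal-observer models of statistical learning in binary sequences.
    Observers estimate item frequency, alternation frequency, or the matrix of
    transition probabilities between successive items, under perfect, windowed,
    leaky (exponential forgetting), or dynamic-belief (change-point hidden
    Markov model) evidence integration, and emit per-trial predictions with
    Shannon surprise and predictive entropy in bits. Includes simulation
    protocols for classic sequential-effect experiments (pattern trees, streak
    violations, repetition/alternation codes, randomness judgments), and a
    fitting layer mapping theoretical surprise onto pattern-level data via an
    offset/scale least-squares fit, grid search over the integration parameter,
    BIC model comparison, and leave-one-out predictive accuracy and
    model-recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
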