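# seqsurprise

Bayesian ideal observers for statistical learning in binary sequences.

When people watch a stream of two possible events — tones, flashes, heads
and tails — their brains continuously form expectations about the next
event. Reaction times, P300-like electrophysiological responses, and
judgments of "how random does this look?" all track those expectations.
`seqsurprise` implements a family of ideal-observer models of this process
and the simulation protocols used to compare them against pattern-level
behavioral and electrophysiological summaries. It is aimed at computational
cognitive scientists and psychophysicists who want trial-by-trial surprise
regressors, pattern-tree simulations, or model comparison over learning
hypotheses.

## The models

A sequence `y_1:t` of symbols X and Y is observed one item at a time. An
observer is defined by two choices:

**What is learned** (the estimated statistic θ):

* *item frequency* — θ = p(X), one dimension;
* *alternation frequency* — θ = p(y_t ≠ y_{t−1}), one dimension;
* *transition probabilities* — θ = (θ_X|Y, θ_Y|X), the two conditional
  probabilities of each item given the previous one. Item and alternation
  frequency are 1-D projections of this 2-D space.

**How evidence is integrated**:

* *perfect* — all observations count equally. With a flat Beta(1, 1) prior
  the posterior is conjugate: `p(θ | y_1:t) = Beta(N_X + 1, N_Y + 1)` for
  item counts, and a product of two Beta factors for transition counts
  (`N_X|Y` = number of YX pairs, etc.).
* *windowed* — perfect counting restricted to the last N observations.
* *leaky* — the observation k steps behind the most recent one is weighted
  `exp(−k/ω)`; an observation's weight halves every `ω·ln 2` new stimuli
  (≈ 11 stimuli for ω = 16). Weighted counts enter the same conjugate form.
* *dynamic belief* — θ itself may be redrawn from the prior before any
  observation with probability `p_c`. Inference is exact forward filtering
  of the change-point hidden Markov model over a discretized θ grid:
  `w'(θ) ∝ p(y | θ, y_prev) · [(1 − p_c)·w(θ) + p_c·prior(θ)]`.

Every observer emits, for each trial, the predictive probability of the
observed item, its Shannon surprise `−log2 p` (bits), and the entropy of
the next-item prediction (bits) — the model's readout of perceived
randomness. Each non-perfect observer has exactly one free parameter
(N, ω, or `p_c`).

A key structural property: repeating streaks provide twice the evidence of
alternating streaks about the currently relevant transition (XXXXXXX gives
a 6:0 evidence ratio for X→X; XYXYXYX only 3:0 for X→Y), so transition
learners — and only they — expect repetitions to continue more strongly
than alternations, and judge sequences with slightly more than 50%
alternations to be the most random.

## Worked example

```r
library(seqsurprise)

# an observer that learns transition probabilities with a leak of 16 stimuli
obs <- observer("transition", "leaky", omega = 16)
#> <observer> transition statistic, leaky integration (omega = 16 stimuli)

# trial-by-trial predictions on a streak that breaks
run_observer(seq_from_string("XXXXXY"), observer("transition", "perfect"))
#> # A tibble: 6 x 5
#>   trial symbol p_pred surprise entropy
#>   <int>  <int>  <dbl>    <dbl>   <dbl>
#> 1     1      0  0.5      1       1
#> 2     2      0  0.5      1       1
#> 3     3      0  0.667    0.585   0.918
#> 4     4      0  0.75     0.415   0.811
#> 5     5      0  0.8      0.322   0.722
#> 6     6      1  0.167    2.58    0.650
```

The first two predictions are flat (no pairs observed yet); expectations
for another X then build by the Laplace rule, and the streak-breaking Y
draws 2.58 bits of surprise. After seven Xs the observer bets 7/8 on an
eighth:

```r
predict_next(seq_from_string("XXXXXXX"), observer("transition", "perfect"))
#> # A tibble: 1 x 3
#>     p_x   p_y entropy
#> 1 0.875 0.125   0.544
```

Pattern-tree simulation (three 200-stimulus conditions at p(X) = 0.3, 0.5,
0.7, 200 repetitions; mean surprise per 5-stimulus pattern ending in X):

```r
tree <- squires_tree(obs, seed = 1)
tree[tree$length == 1, ]   # tree roots: rarer X, higher surprise
#>   condition length pattern mean_surprise     n   sem
#> 1       0.3      1 X               1.62  11723    NA
#> 2       0.5      1 X               1.05  19406    NA
#> 3       0.7      1 X               0.616 27580    NA
autoplot(tree)
```

Fitting pattern-level data (here the bundled *synthetic* demonstration
dataset, an affine map of simulated surprise plus noise; real P300
datasets are external):

```r
csv <- system.file("extdata", "synthetic_p300_squires.csv",
                   package = "seqsurprise")
fit <- fit_observer_grid(read_pattern_data(csv), "transition", "leaky",
                         param_grid = c(8, 12, 16, 24), seed = 1)
glance(fit)
#>   statistic  integration best_param    mse r.squared   bic  nobs     k
#> 1 transition leaky               16 0.0143     0.994 -192.    48     3
```

The grid search recovers the generating leak (ω = 16) and reports the MSE
of the offset/scale map, R², and `BIC = n·log(MSE) + k·log(n)` with k
counting the two linear parameters plus the observer's internal one.
`loo_accuracy()` and `model_recovery()` add leave-one-out predictive
accuracy and cross-model recovery matrices; `huettel_streaks()`,
`cho_patterns()`, `falk_entropy_curve()` and `changepoint_demo()` cover the
streak, order-effect, randomness-judgment and volatility protocols. Each
result type has an `autoplot()` method, and fitted objects support
`tidy()`/`glance()`.

A command-line front end wrapping the same functions ships at
`system.file("cli", "seqsurprise", package = "seqsurprise")` with
subcommands `tree | streaks | ra-patterns | randomness | fig2-demo | fit`.

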