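---
title: "Ideal observers for binary sequences: models, protocols, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal observers for binary sequences: models, protocols, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsurprise)
```

## The inference problem

An observer receives a binary sequence $y_{1:t}$ (symbols X and Y, coded
0/1) one item at a time and maintains a posterior over a generative
statistic $\theta$ via Bayes' rule,
$p(\theta \mid y_{1:t}) \propto p(y_{1:t} \mid \theta)\, p(\theta)$, always
starting from a flat prior. Three hypothesis spaces are supported:

* **item frequency**: $\theta_X = p(X)$, one dimension;
* **alternation frequency**: $\theta_{alt} = p(y_t \ne y_{t-1})$, one
  dimension. An alternation learner is *exactly* an item learner run on
  the sequence recoded pairwise as repetitions (R) and alternations (A);
  `recode_alternation()` performs the recoding, and the package tests
  enforce the equivalence for every integration scheme.
* **transition probabilities**:
  $\theta = (\theta_{X|Y}, \theta_{Y|X})$, two dimensions. The likelihood
  factorizes into two independent Bernoulli strands, one per conditioning
  symbol, so the posterior is a product of two Beta distributions. The
  first observation carries likelihood $1/2$ (its "transition" is
  undefined), so the first prediction of every observer is exactly 1/2.

### Fixed belief: counting with a conjugate prior

Under the assumption that $\theta$ never changes, inference reduces to
event counting. With counts $N_X, N_Y$ (items) or the four pair counts
$N_{X|X}, N_{Y|X}, N_{X|Y}, N_{Y|Y}$ (where $N_{X|Y}$ counts YX pairs),
the posterior is $\mathrm{Beta}(N+1, N'+1)$ per dimension, and the
one-step-ahead prediction is the posterior mean — the Laplace rule of
succession, $(N+1)/(N+N'+2)$. `predictive_fixed()` uses this closed form
rather than a point estimate; a test verifies it against numerical
integration of the predictive integral.

Three counting schemes modulate non-stationarity:

* **perfect** — all events weight 1 (no free parameter);
* **windowed** — only events inside the last $N$ stimuli count; a window
  of $N$ stimuli contains $N-1$ complete pairs, which is how the window
  applies to the transition and alternation statistics;
* **leaky** — the event $k$ steps behind the most recent one weighs
  $e^{-k/\omega}$, with the most recent at $k = 0$, weight 1. This
  indexing makes the half-life statement exact: a weight is halved after
  $\omega \ln 2$ newer events (≈ 11 stimuli for $\omega = 16$). For pair
  statistics the leak runs over pair positions. Weighted counts are
  plugged into the same `+1` conjugate form — the prior is added after
  weighting, so the leak is purely a modification of counting.

`count_events()` exposes the counts themselves;
`run_observer()` returns the per-trial prediction trace with surprise
$-\log_2 p$ and predictive entropy
$H(p) = -p\log_2 p - (1-p)\log_2(1-p)$, both in bits. Predictions are
floored at machine epsilon before the log; conjugate predictives never
reach 0, so the floor is inert in normal use.

### Dynamic belief: change-point filtering on a grid

The dynamic-belief observer assumes that before every observation, with
probability $p_c$, $\theta$ is redrawn from the flat prior. Exact
inference is forward filtering of the resulting hidden Markov model:

$$w_{t+1}(\theta) \propto p(y_{t+1} \mid \theta, y_t)\,
  \left[(1 - p_c)\, w_t(\theta) + p_c\, p_0(\theta)\right],$$

with the prediction integrating the likelihood over the same mixed
distribution. The integral is discretized on a midpoint grid over
$(0,1)^d$ — no atoms at exactly 0 or 1 — with default resolution 100 for
the 1-D statistics and 50 per dimension for transitions. The joint is
renormalized after every step (underflow control; the posterior is the
normalized joint). Two facts anchor correctness, and both are enforced in
tests: with $p_c = 0$ the filter reproduces the conjugate posterior
evaluated on the grid to machine precision, and for short sequences
(length ≤ 8) it equals explicit marginalization over all $2^{t-1}$ change
configurations to a relative error below $10^{-10}$.

Grid resolution was chosen so that results are stable to doubling it; the
oracle tests run at resolutions as low as 3–8 and the protocol runs at
50–100, and predictions differ from the conjugate closed form by
$O(m^{-2})$ quadrature error. Larger $p_c$ never produces a more extreme
prediction after a consistent run (monotone forgetting; tested
numerically), and the prediction never loses the volatility floor
$p_c \times$ prior predictive.

Leaky integration is a close approximation to dynamic belief: once the
leak is fitted to the volatility, surprise traces of the two observers
correlate above 0.95 on random sequences. The correspondence is between
*fitted* parameters — a nominal pairing such as $\omega = 16$ with
$p_c = 0.013$ yields a visibly lower correlation (≈ 0.92), which is why
the package treats the two integration styles as distinct models rather
than interchangeable parameterizations.

## Simulation protocols

All protocols take an `observer()` and a single integer seed; every
random draw derives from that seed, so outputs are byte-reproducible.
The default sizes are the study conditions of the experiments they
emulate, and the package's acceptance checks run them at exactly these
sizes.

**Pattern trees** (`squires_tree()`): three conditions with global
p(X) = 0.3, 0.5, 0.7; 200 stimuli per sequence; 200 repetitions; mean
surprise pooled at the end of every complete pattern of five stimuli
terminating in X (16 patterns × 3 conditions = 48 cells; the four-stimulus
dialect gives 8 × 3 = 24). The 0.3 condition is simulated directly with
p(X) = 0.3 and analyzed on patterns ending in X, which by label symmetry
equals analyzing the rare item of a 0.7 condition. Positions earlier than
the pattern length are discarded (no complete pattern exists there).
Shorter patterns are reported for plotting as frequency-weighted averages
of the full-length cells, but only full-length cells ever enter the
fitting layer: shorter patterns are deterministic aggregates of longer
ones and would double-count the global frequency effect.

**Streaks** (`huettel_streaks()`): one unbiased sequence of $10^5$
stimuli; each trial with at least one preceding pair is classified by the
maximal run of consistent repetition or alternation pairs immediately
before it (length counted in items, minimum 2, capped at 8 — runs longer
than the cap are binned at 8), and by whether the trial continued or
violated that run. A trial is classified only by its maximal consistent
preceding streak; overlapping shorter classifications are not counted
twice. One structural subtlety is worth knowing when reading the output:
for *odd-length alternation* streaks the repetition pair that terminated
the preceding run supports the violation outcome, so the
violation-minus-continuation gap wobbles with parity (and can dip slightly
negative at length 3 for strong leaks) even though its trend over length
is robustly positive. Repetition streaks show no such parity effect, and
their gap grows more steeply — the evidence-asymmetry signature specific
to transition learning.

**Repetition/alternation codes** (`cho_patterns()`): same sequence sizes;
surprise sorted by the 16 codes formed by the four pairs among the last
five stimuli, most recent pair last, reported in the conventional order
(RRRR first, AAAA last, codes ending in a repetition before codes ending
in an alternation).

**Randomness judgments** (`falk_entropy_curve()`): sequences of 21
stimuli at alternation probabilities 0.1–1.0; the perceived randomness of
a sequence is the entropy of the prediction about the 22nd item;
$10^4$ sequences per cell. Pair-wise Bernoulli generation is the default;
`generation = "exact_ratio"` instead fixes the alternation count at
`round(p_alt * 20)` and shuffles positions, matching designs where
alternation *ratios* were controlled exactly. `mode =
"average_over_sequence"` averages entropy over the within-sequence
predictions (trials 2 through 22) instead of using only the last one; it
yields the same qualitative curves and is kept for robustness checks.

**Change-point demonstration** (`changepoint_demo()`): a 300-trial
sequence whose transition matrix reverses at trial 150
($\theta_{X|Y} = 2/3 \leftrightarrow 1/3$), run under perfect, leaky, and
dynamic observers with per-trial posterior marginals for heat-map
display. The second half continues from the last symbol of the first
(there is one sequence, not two concatenated ones).

### What the generator does and does not emulate

The synthetic sequences are exactly the generative processes the models
assume: i.i.d. items, i.i.d. alternation indicators, or a first-order
Markov chain with optional uniform redraws of the whole transition
matrix. Passing tests therefore show that the inference machinery is
correct and that the documented qualitative effects follow from it — not
that real brains produce these effects, and not that the models fit any
particular empirical dataset: real P300/reaction-time data live on an
arbitrary measurement scale (hence the offset/scale map below), contain
structured noise, drifts and finite-session effects that the generator
deliberately omits. The item generator uses a label-equivariant
thresholding rule so that swapping p(X) for 1 − p(X) provably just swaps
the labels, which is the symmetry the "virtual condition" analysis relies
on.

## Fitting layer

Theoretical surprise has no intrinsic scale, so model values $s$ are
mapped onto data $d$ by $d \approx \alpha + \beta s$, fitted by
closed-form (optionally weighted) least squares; `fit_linear_map()`
reports MSE and $R^2$. If the model values are constant the scale is
undefined: the fit is flagged degenerate with scale 0 and $R^2$ 0 by
convention. The default is unweighted — every pattern cell counts
equally; `weighted = TRUE` weights cells by their simulated pattern
frequency as a robustness variant.

`fit_observer_grid()` sweeps the observer's single internal parameter:
for each grid value it simulates the pattern-tree protocol, fits the
linear map, and records the MSE; the best parameter is the arg-min, with
ties broken toward the smallest value (deterministic). The simulated
sequences depend only on the seed — not on the parameter — so one set of
sequences is shared across the whole grid and the MSE curve is noiseless
in the parameter. Model comparison uses
$\mathrm{BIC} = n \log(\mathrm{MSE}) + k \log(n)$ with natural
logarithms (the Gaussian-residual least-squares form), where $k$ counts
the two linear parameters plus the internal ones (0 for perfect
integration, 1 otherwise); `bic_table()` reports differences relative to
the best model. A zero MSE (exact self-fit) leaves the BIC undefined and
is flagged rather than computed.

`loo_accuracy()` refits *all* parameters — offset, scale, and the
internal parameter — on $n-1$ cells per fold and scores the absolute
prediction error on the held-out cell. `model_recovery()` crosses
generating and fitting families: data simulated from each family at its
stated parameter, predicted by every family via the same leave-one-out
procedure. Generating and fitting simulations deliberately use different
seeds, so the diagonal reflects true Monte-Carlo error rather than shared
noise. The expected structure — near-zero diagonal, near-zero recovery of
perfect integration by a leaky learner of the same statistic (the leak
grid extends to 100 so the leak can approach perfect integration), and
clearly positive cross-statistic errors — is asserted in the test suite.
The procedure is directional (fitting leaky data with a perfect model
does *not* give near-zero error), so the matrix is not symmetric.

Empirical datasets enter as a CSV with columns `condition`
(global p(X)), `pattern` (4 or 5 symbols ending in X), and `value`. The
bundled `synthetic_p300_squires.csv` is a *synthetic* demonstration —
simulated transition-observer surprise mapped through an affine transform
plus Gaussian noise — because the real pattern-level values from the
classic studies were digitized from published figures and are not
redistributable. Against such a user-supplied CSV the full comparison
(grid search per family, BIC table, LOO) is a few function calls; the
test suite runs it end to end on the synthetic file.

## Numerical and design choices

* **Surprise sign**: surprise is $-\log_2 p$; an improbable event must
  carry *more* bits.
* **Leak indexing** (weight 1 at $k = 0$) makes the half-life identity
  exact, as noted above.
* **Degenerate inputs**: sequences must have length ≥ 1; pair statistics
  on length-1 sequences have zero counts and flat predictions; pattern
  operations validate their position arguments.
* **Problem sizes in tests**: unit tests run the protocols at reduced
  sizes (tens of repetitions, $10^3$–$2\times10^4$ stimuli) chosen so
  that Monte-Carlo error is far below the asserted margins; the
  acceptance checks then run the full study sizes ($200 \times 200$
  trees, $10^5$-stimulus streak/code protocols, $10^4$-rep entropy
  curves, 50-draw parameter recovery). Monte-Carlo stability was checked
  by doubling repetition counts during development.
* **Seeds**: every user-facing simulation takes one integer seed and
  derives all draws from it sequentially; callers' RNG state is left
  untouched (`withr::local_seed()`).
* **Mean surprise on a fair coin**: a forgetful observer's long-run mean
  surprise is a cross-entropy and sits slightly *above* 1 bit (≈ 1.03 at
  $\omega = 16$), approaching 1 only as the leak vanishes — a Jensen
  effect worth remembering when sanity-checking traces.

## Known limitations

* Binary alphabets only; the transition machinery generalizes to more
  symbols in principle but is not implemented here.
* No hierarchical inference over $p_c$ or $\omega$ themselves; they are
  swept or fitted, not learned.
* The descriptive (non-Bayesian) comparison models from the original
  P300 literature are out of scope; the BIC table compares the observer
  families implemented here.
* `falk_entropy_curve()` covers the leaky fixed-belief family (the sweep
  the protocol calls for); dynamic-belief entropy curves can be obtained
  via `predict_next()` per sequence at higher cost.
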