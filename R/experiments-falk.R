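# Randomness-judgment protocol: short sequences of 21 stimuli with varying
# alternation frequency; the perceived randomness of a sequence is the
# entropy of the observer's prediction about the next (22nd) stimulus,
# averaged over many sequences.

#' Predictive-entropy curve over alternation frequencies
#'
#' For each alternation probability and each leak value, generates `n_reps`
#' sequences of `seq_len` stimuli, runs a leaky fixed-belief observer of the
#' given statistic, and averages the entropy of the prediction about the
#' next stimulus. `mode = "average_over_sequence"` instead averages entropy
#' across the successive within-sequence predictions (trials 2..seq_len+1),
#' which yields the same qualitative results. `generation = "exact_ratio"`
#' fixes the number of alternations to `round(p_alt * (seq_len - 1))` and
#' shuffles their positions, instead of i.i.d. pair-wise draws.
#'
#' @param statistic `"transition"`, `"item"`, or `"alternation"`.
#' @param omega Vector of leak values to sweep.
#' @param p_alt Vector of alternation probabilities.
#' @param seq_len Stimuli per sequence.
#' @param n_reps Sequences per (p_alt, omega) cell.
#' @param seed Integer seed.
#' @param mode `"last_prediction"` (default) or `"average_over_sequence"`.
#' @param generation `"bernoulli"` (default) or `"exact_ratio"`.
#' @return An `entropy_curve` tibble with columns `statistic`, `omega`,
#'   `p_alt`, `mean_entropy`, `sem`, `n`.
#' @examples
#' falk_entropy_curve("transition", omega = 16, n_reps = 200, seed = 1)
#' @export
falk_entropy_curve <- function(statistic = c("transition", "item",
                                             "alternation"),
                               omega = c(4, 8, 16),
                               p_alt = seq(0.1, 1, by = 0.1),
                               seq_len = 21, n_reps = 1e4, seed = NULL,
                               mode = c("last_prediction",
                                        "average_over_sequence"),
                               generation = c("bernoulli", "exact_ratio")) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  generation <- match.arg(generation)
  seq_len <- check_count(seq_len, "seq_len", min = 3L)
  n_reps <- check_count(n_reps, "n_reps")
  stopifnot(all(omega > 0), all(p_alt >= 0 & p_alt <= 1))
  if (!is.null(seed)) withr::local_seed(seed)

  res <- purrr::map(p_alt, function(pa) {
    ymat <- alt_sequence_matrix(pa, seq_len, n_reps, generation)
    purrr::map(omega, function(om) {
      h <- batch_entropy(ymat, statistic, om, mode)
      tibble::tibble(statistic = statistic, omega = om, p_alt = pa,
                     mean_entropy = mean(h), sem = sem(h), n = n_reps)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(res, class = c("entropy_curve", class(res)), seq_len = seq_len,
            n_reps = n_reps, mode = mode, generation = generation,
            seed = seed)
}

# Matrix of n_reps sequences (rows) of seq_len stimuli (columns).
alt_sequence_matrix <- function(p_alt, seq_len, n_reps, generation) {
  first <- stats::runif(n_reps) < 0.5
  n_pairs <- seq_len - 1L
  alt <- if (generation == "bernoulli") {
    matrix(stats::runif(n_reps * n_pairs) < p_alt, n_reps, n_pairs)
  } else {
    k <- round(p_alt * n_pairs)
    base <- c(rep(TRUE, k), rep(FALSE, n_pairs - k))
    t(vapply(seq_len(n_reps), function(i) sample(base), logical(n_pairs)))
  }
  flips <- cbind(as.integer(first), alt)
  (matrix(cumsum_rows(flips), n_reps, seq_len)) %% 2L
}

cumsum_rows <- function(m) t(apply(m, 1L, cumsum))

# Entropy of the observer's predictions over a batch of sequences, computed
# by running the leaky count recursions column-wise (vectorized over rows).
batch_entropy <- function(ymat, statistic, omega, mode) {
  n_reps <- nrow(ymat)
  seq_len <- ncol(ymat)
  a <- exp(-1 / omega)
  keep_all <- mode == "average_over_sequence"
  hsum <- numeric(n_reps)
  hn <- 0L

  if (statistic == "item") {
    cx <- numeric(n_reps)
    ct <- numeric(n_reps)
    for (t in seq_len(seq_len)) {
      if (keep_all && t >= 2L) {
        p_x <- (cx + 1) / (ct + 2)
        hsum <- hsum + shannon_entropy(p_x)
        hn <- hn + 1L
      }
      cx <- a * cx + (ymat[, t] == 0L)
      ct <- a * ct + 1
    }
    p_x <- (cx + 1) / (ct + 2)
  } else if (statistic == "alternation") {
    calt <- numeric(n_reps)
    ct <- numeric(n_reps)
    for (t in 2:seq_len) {
      if (keep_all) {
        p_alt <- (calt + 1) / (ct + 2)
        hsum <- hsum + shannon_entropy(p_alt)
        hn <- hn + 1L
      }
      calt <- a * calt + (ymat[, t] != ymat[, t - 1L])
      ct <- a * ct + 1
    }
    p_alt <- (calt + 1) / (ct + 2)
    p_x <- ifelse(ymat[, seq_len] == 0L, 1 - p_alt, p_alt)
  } else {
    cxx <- numeric(n_reps); cyx <- numeric(n_reps)
    cxy <- numeric(n_reps); cyy <- numeric(n_reps)
    for (t in 2:seq_len) {
      if (keep_all) {
        hsum <- hsum + shannon_entropy(trans_pred(ymat[, t - 1L], cxx, cyx,
                                                  cxy, cyy))
        hn <- hn + 1L
      }
      from <- ymat[, t - 1L]; to <- ymat[, t]
      cxx <- a * cxx + (from == 0L & to == 0L)
      cyx <- a * cyx + (from == 0L & to == 1L)
      cxy <- a * cxy + (from == 1L & to == 0L)
      cyy <- a * cyy + (from == 1L & to == 1L)
    }
    p_x <- trans_pred(ymat[, seq_len], cxx, cyx, cxy, cyy)
  }

  h_last <- shannon_entropy(p_x)
  if (keep_all) (hsum + h_last) / (hn + 1L) else h_last
}

trans_pred <- function(last, cxx, cyx, cxy, cyy) {
  ifelse(last == 0L,
         (cxx + 1) / (cxx + cyx + 2),
         (cxy + 1) / (cxy + cyy + 2))
}
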