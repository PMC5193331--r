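# Pattern-tree protocol: sequences of 200 stimuli at global P(X) of 0.3, 0.5
# and 0.7, repeated 200 times; surprise averaged at the end of every complete
# pattern of `pattern_len` stimuli terminating with X.

#' Simulate a surprise tree over stimulus patterns
#'
#' For each condition (global probability of X), generates `n_reps`
#' sequences of `n_stim` stimuli, runs the observer, and averages surprise
#' at the end of every pattern of `pattern_len` stimuli ending in X
#' (2^(pattern_len - 1) patterns per condition; positions earlier than
#' `pattern_len` are discarded since no complete pattern exists there).
#' Shorter patterns (lengths 1 to `pattern_len - 1`) are also reported for
#' plotting, as frequency-weighted averages of the full-length cells; only
#' full-length cells should feed any fitting.
#'
#' @param obs An [observer()].
#' @param n_stim Stimuli per sequence.
#' @param n_reps Number of simulated sequences per condition.
#' @param conditions Global probabilities of X.
#' @param pattern_len Length of the full patterns (4 or 5).
#' @param seed Integer seed for the whole protocol.
#' @return A `surprise_tree` tibble with columns `condition`, `length`,
#'   `pattern`, `mean_surprise`, `n`, `sem`.
#' @examples
#' squires_tree(observer("transition", "leaky", omega = 16),
#'              n_reps = 10, seed = 1)
#' @export
squires_tree <- function(obs, n_stim = 200, n_reps = 200,
                         conditions = c(0.3, 0.5, 0.7), pattern_len = 5,
                         seed = NULL) {
  stopifnot(inherits(obs, "observer"))
  if (!pattern_len %in% c(4, 5)) rlang::abort("`pattern_len` must be 4 or 5")
  n_stim <- check_count(n_stim, "n_stim", min = as.integer(pattern_len))
  n_reps <- check_count(n_reps, "n_reps")
  seqs <- simulate_condition_sequences(conditions, n_stim, n_reps, seed)
  cells <- pattern_cells(seqs, obs, pattern_len)
  out <- add_shorter_patterns(cells, pattern_len)
  structure(out, class = c("surprise_tree", class(out)), observer = obs,
            n_stim = n_stim, n_reps = n_reps, pattern_len = pattern_len,
            seed = seed)
}

# Generate the full set of sequences for all conditions and repetitions.
# Returns a list of lists of integer symbol vectors, keyed by condition.
simulate_condition_sequences <- function(conditions, n_stim, n_reps, seed) {
  if (!is.null(seed)) withr::local_seed(seed)
  lapply(stats::setNames(conditions, conditions), function(p_x) {
    lapply(seq_len(n_reps), function(i) {
      symbols_of(sim_item_seq(p_x, n_stim))
    })
  })
}

# Mean surprise per full-length pattern ending in X, pooled over sequences.
pattern_cells <- function(seqs, obs, pattern_len) {
  n_keys <- 2L^pattern_len
  res <- purrr::imap(seqs, function(reps, cond) {
    acc_sum <- numeric(n_keys)
    acc_sumsq <- numeric(n_keys)
    acc_n <- numeric(n_keys)
    for (y in reps) {
      p <- if (obs$integration == "dynamic") {
        dynamic_trace_probs(y, obs)$p
      } else {
        fixed_trace_probs(y, obs)
      }
      s <- surprise(p)
      keys <- lastk_keys(y, pattern_len)
      ok <- !is.na(keys) & y == 0L # complete patterns terminating with X
      f <- factor(keys[ok], levels = 0:(n_keys - 1L))
      acc_sum <- acc_sum + vapply(split(s[ok], f), sum, 0)
      acc_sumsq <- acc_sumsq + vapply(split(s[ok]^2, f), sum, 0)
      acc_n <- acc_n + tabulate(f, nbins = n_keys)
    }
    keep <- acc_n > 0
    key <- (0:(n_keys - 1L))[keep]
    m <- acc_sum[keep] / acc_n[keep]
    v <- pmax(acc_sumsq[keep] / acc_n[keep] - m^2, 0)
    tibble::tibble(
      condition = as.numeric(cond),
      length = pattern_len,
      pattern = key_to_pattern(key, pattern_len),
      mean_surprise = unname(m),
      n = unname(acc_n[keep]),
      sem = unname(sqrt(v / acc_n[keep]))
    )
  })
  dplyr::bind_rows(res)
}

# Shorter patterns are weighted averages of the full-length cells sharing
# the same terminal suffix.
add_shorter_patterns <- function(cells, pattern_len) {
  shorter <- purrr::map(seq_len(pattern_len - 1L), function(len) {
    cells |>
      dplyr::mutate(
        length = len,
        pattern = substr(.data$pattern, pattern_len - len + 1L, pattern_len)
      ) |>
      dplyr::group_by(.data$condition, .data$length, .data$pattern) |>
      dplyr::summarise(
        mean_surprise = sum(.data$mean_surprise * .data$n) / sum(.data$n),
        n = sum(.data$n),
        sem = NA_real_,
        .groups = "drop"
      )
  })
  dplyr::bind_rows(cells, dplyr::bind_rows(shorter)) |>
    dplyr::arrange(.data$condition, .data$length, .data$pattern)
}
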