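# Generative processes for binary sequences: biased coin on items, biased coin
# on alternations, and a two-coin Markov process with optional sudden changes
# of the whole transition matrix.

#' Simulate a sequence of independent items from a biased coin
#'
#' Each trial is an independent draw with `P(X) = p_x`. The draw is made by
#' thresholding one uniform per trial in a label-equivariant way, so that for
#' any seed, `sim_item_seq(p)` and `sim_item_seq(1 - p)` are identical up to
#' swapping the two labels (exact for `p != 0.5`).
#'
#' @param p_x Probability of symbol X on each trial.
#' @param n_stim Sequence length (number of trials).
#' @param seed Optional integer seed; when given, the RNG state of the caller
#'   is left untouched.
#' @return A sequence tibble with columns `trial` and `symbol`.
#' @examples
#' sim_item_seq(0.7, 10, seed = 1)
#' @export
sim_item_seq <- function(p_x, n_stim, seed = NULL) {
  p_x <- check_probability(p_x, "p_x")
  n_stim <- check_count(n_stim, "n_stim")
  if (!is.null(seed)) withr::local_seed(seed)
  u <- stats::runif(n_stim)
  # Label-equivariant thresholding: the majority label claims u < max(p, 1-p).
  if (p_x >= 0.5) {
    symbol <- ifelse(u < p_x, 0L, 1L)
  } else {
    symbol <- ifelse(u < 1 - p_x, 1L, 0L)
  }
  seq_tbl(symbol)
}

#' Simulate a sequence from a biased coin on alternations
#'
#' The first symbol is drawn uniformly; each subsequent symbol differs from
#' its predecessor with probability `p_alt`.
#'
#' @param p_alt Probability that consecutive symbols differ.
#' @inheritParams sim_item_seq
#' @param first Optional first symbol (0/1 or "X"/"Y"); drawn uniformly when
#'   `NULL`.
#' @return A sequence tibble.
#' @examples
#' sim_alt_seq(1, 5, seed = 1, first = "X") # forced alternation: XYXYX
#' @export
sim_alt_seq <- function(p_alt, n_stim, seed = NULL, first = NULL) {
  p_alt <- check_probability(p_alt, "p_alt")
  n_stim <- check_count(n_stim, "n_stim")
  if (!is.null(seed)) withr::local_seed(seed)
  y <- integer(n_stim)
  y[1] <- if (is.null(first)) {
    as.integer(stats::runif(1) < 0.5)
  } else {
    as_symbol_int(first)
  }
  if (n_stim > 1L) {
    flip <- stats::runif(n_stim - 1L) < p_alt
    y[-1] <- (y[1] + cumsum(flip)) %% 2L
  }
  seq_tbl(y)
}

#' Simulate a sequence from a two-coin Markov process
#'
#' The process is parameterized by the two transition probabilities
#' `theta_x_given_y = P(next = X | current = Y)` and
#' `theta_y_given_x = P(next = Y | current = X)`. The first symbol is drawn
#' uniformly (or fixed via `first`). When `p_change > 0`, before every trial
#' after the first, with probability `p_change` both transition probabilities
#' are jointly redrawn uniformly on \[0, 1\]; trials at which this happened
#' are flagged in a logical `change` column.
#'
#' @param theta_x_given_y,theta_y_given_x Transition probabilities.
#' @inheritParams sim_alt_seq
#' @param p_change Per-trial probability of a sudden change of the whole
#'   transition matrix (0 = stationary).
#' @return A sequence tibble with columns `trial`, `symbol`, `change`; the
#'   trial indices of changes are also stored in attribute `change_times`.
#' @examples
#' sim_markov_seq(2 / 3, 1 / 3, 20, seed = 1)
#' @export
sim_markov_seq <- function(theta_x_given_y, theta_y_given_x, n_stim,
                           seed = NULL, p_change = 0, first = NULL) {
  txy <- check_probability(theta_x_given_y, "theta_x_given_y")
  tyx <- check_probability(theta_y_given_x, "theta_y_given_x")
  p_change <- check_probability(p_change, "p_change")
  if (p_change >= 1) rlang::abort("`p_change` must be < 1")
  n_stim <- check_count(n_stim, "n_stim")
  if (!is.null(seed)) withr::local_seed(seed)

  y <- integer(n_stim)
  change <- logical(n_stim)
  y[1] <- if (is.null(first)) {
    as.integer(stats::runif(1) < 0.5)
  } else {
    as_symbol_int(first)
  }
  if (n_stim > 1L) {
    for (t in 2:n_stim) {
      if (p_change > 0 && stats::runif(1) < p_change) {
        # The full transition matrix changes suddenly: joint uniform redraw.
        txy <- stats::runif(1)
        tyx <- stats::runif(1)
        change[t] <- TRUE
      }
      p_switch <- if (y[t - 1L] == 0L) tyx else txy
      y[t] <- if (stats::runif(1) < p_switch) 1L - y[t - 1L] else y[t - 1L]
    }
  }
  out <- seq_tbl(y)
  out$change <- change
  attr(out, "change_times") <- which(change)
  out
}

#' Recode a sequence as repetitions and alternations
#'
#' Each consecutive pair of symbols is recoded as a repetition (R, code 0)
#' when the two symbols are equal, or an alternation (A, code 1) when they
#' differ. An observer estimating alternation frequency is exactly an item
#' observer running on this recoded sequence.
#'
#' @param data A sequence tibble of length >= 2.
#' @return A tibble with columns `trial` (position of the second element of
#'   each pair), `code` (0 = R, 1 = A) and `letter` ("R"/"A").
#' @examples
#' recode_alternation(seq_from_string("XYXYY")) # AAAR
#' @export
recode_alternation <- function(data) {
  y <- symbols_of(data)
  if (length(y) < 2L) rlang::abort("need at least 2 symbols to recode pairs")
  code <- as.integer(diff(y) != 0L)
  tibble::tibble(
    trial = seq_along(code) + 1L,
    code = code,
    letter = c("R", "A")[code + 1L]
  )
}
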