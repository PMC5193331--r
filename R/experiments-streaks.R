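# Streak and repetition/alternation-code protocols on long unbiased
# sequences: a single sequence of 1e5 stimuli with P(X) = 0.5.

#' Mean surprise by streak type, length, and outcome
#'
#' Generates one long unbiased sequence, runs the observer, and sorts
#' surprise by whether the local stimulus history formed a streak of
#' repetitions or of alternations, the streak length in items (capped at
#' `max_len`), and whether the current stimulus continued or violated it.
#'
#' @inheritParams squires_tree
#' @param n_stim Sequence length.
#' @param p_x Global probability of X.
#' @param max_len Cap on streak length (in items).
#' @return A `streak_summary` tibble with columns `streak`, `length`,
#'   `outcome`, `mean_surprise`, `n`, `sem`.
#' @examples
#' huettel_streaks(observer("transition", "leaky", omega = 6),
#'                 n_stim = 2000, seed = 1)
#' @export
huettel_streaks <- function(obs, n_stim = 1e5, p_x = 0.5, max_len = 8,
                            seed = NULL) {
  stopifnot(inherits(obs, "observer"))
  max_len <- check_count(max_len, "max_len", min = 2L)
  if (max_len > 8L) rlang::abort("`max_len` must be <= 8")
  y <- symbols_of(sim_item_seq(p_x, n_stim, seed = seed))
  s <- trace_surprise(y, obs)
  cls <- streak_table(y, max_len = max_len)
  cls$s <- s[cls$trial]
  out <- cls |>
    dplyr::group_by(.data$streak, .data$length, .data$outcome) |>
    dplyr::summarise(
      mean_surprise = mean(.data$s), n = dplyr::n(), sem = sem(.data$s),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$streak, .data$length, .data$outcome)
  structure(out, class = c("streak_summary", class(out)), observer = obs,
            n_stim = n_stim, p_x = p_x, seed = seed)
}

#' Mean surprise by repetition/alternation pattern of five stimuli
#'
#' Generates one long unbiased sequence, runs the observer, and sorts
#' surprise by the 16 possible repetition (R) / alternation (A) codes of the
#' four pairs formed by the last five stimuli (most recent pair last).
#'
#' @inheritParams huettel_streaks
#' @return An `ra_summary` tibble with columns `code` (factor in canonical
#'   order, RRRR first, AAAA last), `mean_surprise`, `n`, `sem`.
#' @examples
#' cho_patterns(observer("transition", "leaky", omega = 3),
#'              n_stim = 2000, seed = 1)
#' @export
cho_patterns <- function(obs, n_stim = 1e5, p_x = 0.5, seed = NULL) {
  stopifnot(inherits(obs, "observer"))
  y <- symbols_of(sim_item_seq(p_x, n_stim, seed = seed))
  s <- trace_surprise(y, obs)
  keys <- ra_keys(y)
  ok <- !is.na(keys)
  out <- tibble::tibble(code_key = keys[ok], s = s[ok]) |>
    dplyr::mutate(code = factor(ra_key_to_code(.data$code_key),
                                levels = RA_LEVELS)) |>
    dplyr::group_by(.data$code) |>
    dplyr::summarise(
      mean_surprise = mean(.data$s), n = dplyr::n(), sem = sem(.data$s),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$code)
  structure(out, class = c("ra_summary", class(out)), observer = obs,
            n_stim = n_stim, p_x = p_x, seed = seed)
}

trace_surprise <- function(y, obs) {
  p <- if (obs$integration == "dynamic") {
    dynamic_trace_probs(y, obs)$p
  } else {
    fixed_trace_probs(y, obs)
  }
  surprise(p)
}
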