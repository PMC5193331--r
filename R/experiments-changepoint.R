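# Demonstration of the three inference styles on a sequence whose transition
# matrix reverses abruptly half-way: the first half is generated with
# p(X|Y) = 1 - p(Y|X) = 2/3 and the second half with p(X|Y) = 1 - p(Y|X) = 1/3.

#' Change-point demonstration of the three inference styles
#'
#' Generates a sequence with one abrupt reversal of the transition matrix at
#' `change_at`, then runs perfect, leaky, and dynamic-belief transition
#' observers, returning their per-trial posterior marginals over the two
#' transition probabilities (heat-map view) and their prediction traces.
#'
#' @param seed Integer seed.
#' @param n_stim Total sequence length.
#' @param change_at Trial of the change (first regime covers `1..change_at`).
#' @param theta_first `c(theta_x_given_y, theta_y_given_x)` of the first
#'   regime; the second regime uses the reversed pair.
#' @param omega Leak of the leaky observer.
#' @param p_change Change probability of the dynamic observer.
#' @param resolution Posterior grid resolution per dimension.
#' @return A `changepoint_demo` object: list with elements `sequence` (the
#'   sequence tibble), `traces` (combined prediction traces with a `model`
#'   column) and `posteriors` (tibble `model`, `trial`, `dim`, `theta`, `w`).
#' @examples
#' demo <- changepoint_demo(seed = 1, n_stim = 60, change_at = 30,
#'                          resolution = 20)
#' @export
changepoint_demo <- function(seed = NULL, n_stim = 300, change_at = 150,
                             theta_first = c(2 / 3, 1 / 3), omega = 16,
                             p_change = 1 / 75, resolution = 50) {
  n_stim <- check_count(n_stim, "n_stim", min = 4L)
  change_at <- check_count(change_at, "change_at", min = 2L)
  stopifnot(change_at < n_stim)
  if (!is.null(seed)) withr::local_seed(seed)

  y <- integer(n_stim)
  y[seq_len(change_at)] <- symbols_of(
    sim_markov_seq(theta_first[1], theta_first[2], change_at)
  )
  # second regime continues from the last symbol with the reversed matrix
  txy <- theta_first[2]
  tyx <- theta_first[1]
  for (t in (change_at + 1L):n_stim) {
    p_switch <- if (y[t - 1L] == 0L) tyx else txy
    y[t] <- if (stats::runif(1) < p_switch) 1L - y[t - 1L] else y[t - 1L]
  }
  seq_data <- seq_tbl(y)
  seq_data$change <- seq_along(y) == change_at + 1L

  models <- list(
    perfect = observer("transition", "perfect"),
    leaky = observer("transition", "leaky", omega = omega),
    dynamic = observer("transition", "dynamic", p_change = p_change,
                       resolution = resolution)
  )
  traces <- purrr::imap(models, function(obs, nm) {
    tr <- run_observer(seq_data, obs)
    tr$model <- nm
    tibble::as_tibble(tr)
  }) |> dplyr::bind_rows()
  posteriors <- purrr::imap(models, function(obs, nm) {
    pt <- posterior_trace(seq_data, obs, resolution = resolution)
    pt$model <- nm
    pt
  }) |> dplyr::bind_rows()

  structure(
    list(sequence = seq_data, traces = traces, posteriors = posteriors,
         change_at = change_at, theta_first = theta_first),
    class = "changepoint_demo"
  )
}

#' @export
print.changepoint_demo <- function(x, ...) {
  cat(sprintf(
    "<changepoint_demo> %d trials, change at trial %d (theta %0.2f/%0.2f)\n",
    nrow(x$sequence), x$change_at, x$theta_first[1], x$theta_first[2]
  ))
  cat("models:", paste(unique(x$traces$model), collapse = ", "), "\n")
  invisible(x)
}
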