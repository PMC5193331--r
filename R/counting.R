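# Event counting under perfect, windowed, and leaky integration.
#
# Leak convention: the observation at distance k behind the most recent
# counted one has weight exp(-k / omega); the most recent has k = 0, weight 1.
# With this convention the weight of an observation is halved after
# omega * log(2) new observations. Perfect integration is the window limit
# N >= number of observations.

#' Count events in a binary sequence under an integration scheme
#'
#' Counts items (`N_X`, `N_Y`), transitions (`N_{X|X}`, `N_{Y|X}`,
#' `N_{X|Y}`, `N_{Y|Y}`, where `N_{X|Y}` is the number of Y->X pairs), or
#' repetitions/alternations, using all observations up to trial `upto`.
#' Windowed counting uses only the last `n` observations; leaky counting
#' weights the observation `k` steps behind the most recent by
#' `exp(-k / omega)`. Pair events are weighted by pair position: the most
#' recent complete pair has weight 1.
#'
#' @param data A sequence tibble.
#' @param statistic One of `"item"`, `"transition"`, `"alternation"`.
#' @param integration One of `"perfect"`, `"windowed"`, `"leaky"`.
#' @param upto Count events occurring up to and including this trial
#'   (default: whole sequence).
#' @param n Window length (windowed integration only), in observations.
#' @param omega Leak time constant (leaky integration only), in observations.
#' @return A one-row tibble of (possibly real-valued) counts: columns
#'   `n_x`, `n_y` for items; `n_x_given_x`, `n_y_given_x`, `n_x_given_y`,
#'   `n_y_given_y` for transitions; `n_rep`, `n_alt` for alternations.
#' @examples
#' count_events(seq_from_string("XXXXXXX"), "transition") # 6 X->X, 0 X->Y
#' count_events(seq_from_string("XX"), "item", "leaky", omega = 16)
#' @export
count_events <- function(data, statistic = c("item", "transition",
                                             "alternation"),
                         integration = c("perfect", "windowed", "leaky"),
                         upto = NULL, n = NULL, omega = NULL) {
  statistic <- match.arg(statistic)
  integration <- match.arg(integration)
  y <- symbols_of(data)
  if (is.null(upto)) upto <- length(y)
  upto <- check_count(upto, "upto")
  if (upto > length(y)) rlang::abort("`upto` exceeds the sequence length")
  y <- y[seq_len(upto)]
  check_scheme_params(integration, n, omega)

  if (statistic == "item") {
    w <- event_weights(length(y), integration, n, omega)
    return(tibble::tibble(n_x = sum(w[y == 0L]), n_y = sum(w[y == 1L])))
  }

  if (length(y) < 2L) {
    pairs <- integer(0)
    from <- integer(0)
    to <- integer(0)
  } else {
    from <- y[-length(y)]
    to <- y[-1L]
    pairs <- seq_along(from)
  }
  w <- event_weights(length(pairs), integration, n_pairs(integration, n),
                     omega)
  if (statistic == "alternation") {
    alt <- from != to
    return(tibble::tibble(n_rep = sum(w[!alt]), n_alt = sum(w[alt])))
  }
  tibble::tibble(
    n_x_given_x = sum(w[from == 0L & to == 0L]),
    n_y_given_x = sum(w[from == 0L & to == 1L]),
    n_x_given_y = sum(w[from == 1L & to == 0L]),
    n_y_given_y = sum(w[from == 1L & to == 1L])
  )
}

# A window of n observations contains n - 1 complete pairs.
n_pairs <- function(integration, n) {
  if (integration == "windowed") max(n - 1L, 0L) else n
}

check_scheme_params <- function(integration, n, omega) {
  if (integration == "windowed") {
    if (is.null(n)) rlang::abort("windowed integration requires `n`")
    check_count(n, "n")
  } else if (integration == "leaky") {
    if (is.null(omega) || !is.numeric(omega) || omega <= 0) {
      rlang::abort("leaky integration requires `omega` > 0")
    }
  }
  invisible(NULL)
}

# Weight of each of m ordered events (most recent last) under a scheme.
event_weights <- function(m, integration, n, omega) {
  if (m == 0L) return(numeric(0))
  switch(integration,
    perfect = rep(1, m),
    windowed = as.numeric(seq_len(m) > m - n),
    leaky = exp(-(m - seq_len(m)) / omega)
  )
}

# --- Running counts used by the trace computations ---------------------------
# For a binary indicator series x[1..m], return the weighted count of 1s
# among events 1..j for every j (most recent event weight 1).
running_count <- function(x, integration, n = NULL, omega = NULL) {
  m <- length(x)
  if (m == 0L) return(numeric(0))
  switch(integration,
    perfect = cumsum(x),
    windowed = {
      cs <- cumsum(x)
      lag <- c(rep(0, min(n, m)), cs[seq_len(max(m - n, 0L))])
      cs - lag
    },
    leaky = as.numeric(stats::filter(x, exp(-1 / omega),
                                     method = "recursive"))
  )
}
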