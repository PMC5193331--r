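# Run an observer over a sequence, producing a per-trial prediction trace.

#' Run an ideal observer over a sequence
#'
#' Computes, for every trial `t`, the predictive probability the observer
#' assigned to the symbol actually observed at `t` given trials `1..t-1`,
#' together with Shannon surprise (bits) and the entropy of the next-symbol
#' prediction (bits). The first prediction is always 1/2 (flat prior).
#'
#' @param data A sequence tibble (columns `trial`, `symbol`).
#' @param obs An [observer()].
#' @return A `prediction_trace` tibble with columns `trial`, `symbol`,
#'   `p_pred` (probability assigned to the observed symbol), `surprise`
#'   (bits), `entropy` (bits). The observer is attached as attribute
#'   `observer`.
#' @examples
#' run_observer(seq_from_string("XXXX"), observer("item", "perfect"))
#' @export
run_observer <- function(data, obs) {
  stopifnot(inherits(obs, "observer"))
  y <- symbols_of(data)
  p <- if (obs$integration == "dynamic") {
    dynamic_trace_probs(y, obs)$p
  } else {
    fixed_trace_probs(y, obs)
  }
  # entropy of the next-symbol prediction: H is symmetric, so the entropy of
  # the distribution equals H(p assigned to the observed symbol)
  out <- tibble::tibble(
    trial = seq_along(y),
    symbol = y,
    p_pred = p,
    surprise = surprise(p),
    entropy = shannon_entropy(p)
  )
  structure(out, class = c("prediction_trace", class(out)), observer = obs)
}

#' Predict the next symbol after a full sequence
#'
#' Returns the observer's predictive distribution for trial `t + 1` given
#' the whole sequence `1..t`, plus its entropy (the perceived-randomness
#' readout used for judgments of randomness).
#'
#' @inheritParams run_observer
#' @return A one-row tibble with columns `p_x`, `p_y`, `entropy`.
#' @examples
#' predict_next(seq_from_string("XXXXXXX"), observer("transition", "perfect"))
#' @export
predict_next <- function(data, obs) {
  stopifnot(inherits(obs, "observer"))
  y <- symbols_of(data)
  p_x <- if (obs$integration == "dynamic") {
    dynamic_next_prob(y, obs)
  } else {
    fixed_next_prob(y, obs)
  }
  tibble::tibble(p_x = p_x, p_y = 1 - p_x, entropy = shannon_entropy(p_x))
}

#' Per-trial posterior marginals of an observer
#'
#' For dynamic-belief observers, returns the forward-filtered posterior
#' marginal over each estimated dimension after every trial (the heat-map
#' view of the inference). For fixed-belief observers the conjugate Beta
#' posterior density is evaluated on the same midpoint grid.
#'
#' @inheritParams run_observer
#' @param resolution Grid resolution for evaluating fixed-belief densities
#'   (dynamic observers use their own `resolution`).
#' @return A tibble with columns `trial`, `dim`, `theta`, `w` (weights
#'   summing to 1 within each trial and dimension).
#' @export
posterior_trace <- function(data, obs, resolution = 50) {
  stopifnot(inherits(obs, "observer"))
  y <- symbols_of(data)
  if (obs$integration == "dynamic") {
    res <- dynamic_trace_probs(y, obs, keep_posterior = TRUE)
    g <- res$grid$theta
    keep <- res$posteriors
    if (is.matrix(keep)) {
      keep <- list(theta = keep)
      names(keep) <- if (obs$statistic == "item") "theta_x" else "theta_alt"
    }
    out <- purrr::imap(keep, function(mat, nm) {
      tibble::tibble(
        trial = rep(seq_along(y), each = length(g)),
        dim = nm,
        theta = rep(g, times = length(y)),
        w = as.vector(t(mat))
      )
    })
    return(dplyr::bind_rows(out))
  }
  resolution <- check_count(resolution, "resolution", min = 2L)
  g <- (seq_len(resolution) - 0.5) / resolution
  rows <- purrr::map(seq_along(y), function(t) {
    counts <- count_events(seq_tbl(y), obs$statistic, obs$integration,
                           upto = t, n = obs$n, omega = obs$omega)
    post <- beta_posterior(counts)
    purrr::pmap(post, function(dim, shape1, shape2) {
      dens <- dbeta(g, shape1, shape2)
      tibble::tibble(trial = t, dim = dim, theta = g, w = dens / sum(dens))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
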