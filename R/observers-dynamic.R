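# Dynamic-belief inference: the estimated statistic may be redrawn from the
# flat prior with probability p_change before every observation. Forward HMM
# filtering over a discretized theta grid (midpoint rule, no atoms at 0/1):
#
#   w'(theta) proportional to lik(y | theta, y_prev) *
#                             [(1 - p_c) w(theta) + p_c prior(theta)]
#
# and the one-step-ahead prediction integrates the likelihood over the same
# change-mixed distribution. With p_change = 0 this reduces exactly to the
# fixed-belief conjugate posterior evaluated on the grid.

#' Uniform grid prior over the estimated statistic
#'
#' Midpoint-rule discretization of the flat prior: `resolution` equally
#' weighted nodes per dimension at `(i - 1/2) / resolution`, so the grid
#' covers (0, 1) without endpoint atoms. One dimension for the frequency
#' statistics, two (theta_x_given_y, theta_y_given_x) for transitions.
#'
#' @param d Dimensionality (1 or 2).
#' @param resolution Number of grid nodes per dimension (>= 2).
#' @return A `grid_posterior` object: a tibble of nodes with weight column
#'   `w` summing to 1.
#' @examples
#' grid_prior(1, 4) # nodes 1/8, 3/8, 5/8, 7/8, each weight 1/4
#' @export
grid_prior <- function(d, resolution) {
  if (!d %in% c(1, 2)) rlang::abort("`d` must be 1 or 2")
  resolution <- check_count(resolution, "resolution", min = 2L)
  g <- (seq_len(resolution) - 0.5) / resolution
  post <- if (d == 1) {
    tibble::tibble(theta = g, w = 1 / resolution)
  } else {
    grid <- expand.grid(theta_x_given_y = g, theta_y_given_x = g,
                        KEEP.OUT.ATTRS = FALSE)
    tibble::tibble(theta_x_given_y = grid$theta_x_given_y,
                   theta_y_given_x = grid$theta_y_given_x,
                   w = 1 / resolution^2)
  }
  structure(post, class = c("grid_posterior", class(post)),
            d = d, resolution = resolution)
}

# Likelihood of observing symbol y (0/1) at each grid node. For d = 1 the
# node value theta is the probability of the symbol coded 0 (X). For d = 2
# the previous symbol selects the conditioning row of the transition matrix.
grid_likelihood <- function(post, y_new, y_prev = NULL) {
  if (attr(post, "d") == 1) {
    if (y_new == 0L) post$theta else 1 - post$theta
  } else {
    if (is.null(y_prev)) rlang::abort("`y_prev` required for d = 2")
    if (y_prev == 0L) {
      if (y_new == 1L) post$theta_y_given_x else 1 - post$theta_y_given_x
    } else {
      if (y_new == 0L) post$theta_x_given_y else 1 - post$theta_x_given_y
    }
  }
}

#' One forward-filtering step of the dynamic-belief observer
#'
#' @param post A normalized `grid_posterior`.
#' @param y_new Observed symbol (0/1 or "X"/"Y"). For 1-D grids the node
#'   value theta is the probability of the symbol coded 0 (X); feed the
#'   R/A-recoded series (R = 0) to filter an alternation statistic.
#' @param y_prev Previous symbol (2-D grids only).
#' @param p_change Per-trial change probability in `[0, 1)`.
#' @return The updated, renormalized `grid_posterior`.
#' @export
update_grid <- function(post, y_new, p_change, y_prev = NULL) {
  check_grid(post)
  p_change <- check_probability(p_change, "p_change")
  lik <- grid_likelihood(post, as_symbol_int(y_new),
                         if (is.null(y_prev)) NULL else as_symbol_int(y_prev))
  prior_w <- 1 / nrow(post)
  w <- lik * ((1 - p_change) * post$w + p_change * prior_w)
  post$w <- w / sum(w)
  post
}

#' One-step-ahead prediction from a dynamic-belief posterior
#'
#' Integrates the next-symbol likelihood over the change-mixed distribution
#' `(1 - p_change) * posterior + p_change * prior`.
#'
#' @inheritParams update_grid
#' @return The predictive probability that the next symbol is X (for 1-D
#'   alternation grids: that the next pair is an alternation requires mapping
#'   by the caller; this function predicts the event coded by the grid, and
#'   returns the probability of symbol X for item and transition grids).
#' @export
predictive_grid <- function(post, p_change, y_prev = NULL) {
  check_grid(post)
  p_change <- check_probability(p_change, "p_change")
  lik_x <- grid_likelihood(post, 0L,
                           if (is.null(y_prev)) NULL else
                             as_symbol_int(y_prev))
  prior_w <- 1 / nrow(post)
  sum(lik_x * ((1 - p_change) * post$w + p_change * prior_w))
}

#' Marginal posterior over one dimension of a grid posterior
#'
#' @param post A `grid_posterior`.
#' @param margin Dimension name (for 2-D grids: `"theta_x_given_y"` or
#'   `"theta_y_given_x"`); ignored for 1-D grids.
#' @return A tibble with columns `theta` and `w` (weights summing to 1).
#' @export
marginal_grid <- function(post, margin = NULL) {
  check_grid(post)
  if (attr(post, "d") == 1) {
    return(tibble::tibble(theta = post$theta, w = post$w))
  }
  if (is.null(margin)) margin <- "theta_x_given_y"
  stopifnot(margin %in% c("theta_x_given_y", "theta_y_given_x"))
  agg <- rowsum(post$w, group = post[[margin]])
  tibble::tibble(theta = as.numeric(rownames(agg)), w = as.numeric(agg))
}

check_grid <- function(post) {
  if (!inherits(post, "grid_posterior")) {
    rlang::abort("`post` must be a grid_posterior")
  }
  if (abs(sum(post$w) - 1) > 1e-8) {
    rlang::abort("grid posterior is not normalized")
  }
  invisible(post)
}

# --- Per-trial predictive probabilities under dynamic belief -----------------
# Vectorized forward filter over raw weight vectors (no tibble overhead).
# Returns p(y_t | y_{1:t-1}) for every t, and optionally the per-trial
# marginal posteriors for heat-map export.
dynamic_trace_probs <- function(y, obs, keep_posterior = FALSE) {
  t_len <- length(y)
  p_c <- obs$p_change
  m <- obs$resolution
  g <- (seq_len(m) - 0.5) / m
  p <- rep(0.5, t_len)

  if (obs$statistic == "item") {
    prior <- rep(1 / m, m)
    w <- prior
    keep <- if (keep_posterior) matrix(NA_real_, t_len, m) else NULL
    for (t in seq_len(t_len)) {
      mix <- (1 - p_c) * w + p_c * prior
      p_x <- sum(g * mix)
      p[t] <- if (y[t] == 0L) p_x else 1 - p_x
      lik <- if (y[t] == 0L) g else 1 - g
      w <- lik * mix
      w <- w / sum(w)
      if (keep_posterior) keep[t, ] <- w
    }
    return(trace_result(p, keep, list(theta = g)))
  }

  if (obs$statistic == "alternation") {
    prior <- rep(1 / m, m)
    w <- prior # grid over the alternation probability
    keep <- if (keep_posterior) matrix(NA_real_, t_len, m) else NULL
    if (keep_posterior) keep[1, ] <- w
    for (t in 2:max(t_len, 2L)) {
      if (t > t_len) break
      mix <- (1 - p_c) * w + p_c * prior
      p_alt <- sum(g * mix)
      is_alt <- y[t] != y[t - 1L]
      p[t] <- if (is_alt) p_alt else 1 - p_alt
      lik <- if (is_alt) g else 1 - g
      w <- lik * mix
      w <- w / sum(w)
      if (keep_posterior) keep[t, ] <- w
    }
    return(trace_result(p, keep, list(theta = g)))
  }

  # transition statistic: joint grid over (theta_x_given_y, theta_y_given_x)
  gxy <- rep(g, times = m)   # varies fastest
  gyx <- rep(g, each = m)
  prior <- rep(1 / m^2, m^2)
  w <- prior
  keep <- if (keep_posterior) {
    list(theta_x_given_y = matrix(NA_real_, t_len, m),
         theta_y_given_x = matrix(NA_real_, t_len, m))
  } else NULL
  store_marginals <- function(t) {
    wm <- matrix(w, m, m) # rows: theta_x_given_y, cols: theta_y_given_x
    keep$theta_x_given_y[t, ] <<- rowSums(wm)
    keep$theta_y_given_x[t, ] <<- colSums(wm)
  }
  if (keep_posterior) store_marginals(1L) # first obs: likelihood 1/2
  if (t_len >= 2L) {
    for (t in 2:t_len) {
      mix <- (1 - p_c) * w + p_c * prior
      if (y[t - 1L] == 0L) {
        p_x <- sum((1 - gyx) * mix)
        lik <- if (y[t] == 1L) gyx else 1 - gyx
      } else {
        p_x <- sum(gxy * mix)
        lik <- if (y[t] == 0L) gxy else 1 - gxy
      }
      p[t] <- if (y[t] == 0L) p_x else 1 - p_x
      w <- lik * mix
      w <- w / sum(w)
      if (keep_posterior) store_marginals(t)
    }
  }
  trace_result(p, keep, list(theta = g), final_w = w)
}

trace_result <- function(p, keep, grid, final_w = NULL) {
  structure(list(p = p, posteriors = keep, grid = grid, final_w = final_w),
            class = "dynamic_trace_raw")
}

# Predictive probability of X for trial t+1 given a full sequence.
dynamic_next_prob <- function(y, obs) {
  res <- dynamic_trace_probs(y, obs, keep_posterior = FALSE)
  m <- obs$resolution
  g <- (seq_len(m) - 0.5) / m
  p_c <- obs$p_change
  t_len <- length(y)
  if (obs$statistic == "item") {
    w <- refilter_1d(y == 0L, g, p_c)
    mix <- (1 - p_c) * w + p_c * (1 / m)
    return(sum(g * mix))
  }
  if (obs$statistic == "alternation") {
    if (t_len < 2L) return(0.5)
    a <- diff(y) != 0L
    w <- refilter_1d(a, g, p_c)
    mix <- (1 - p_c) * w + p_c * (1 / m)
    p_alt <- sum(g * mix)
    return(if (y[t_len] == 0L) 1 - p_alt else p_alt)
  }
  gxy <- rep(g, times = m)
  gyx <- rep(g, each = m)
  mix <- (1 - p_c) * res$final_w + p_c * (1 / m^2)
  if (y[t_len] == 0L) sum((1 - gyx) * mix) else sum(gxy * mix)
}

# Forward filter of a 1-D binary event series on grid g; returns final weights.
refilter_1d <- function(events, g, p_c) {
  m <- length(g)
  prior <- rep(1 / m, m)
  w <- prior
  for (e in events) {
    mix <- (1 - p_c) * w + p_c * prior
    lik <- if (e) g else 1 - g
    w <- lik * mix
    w <- w / sum(w)
  }
  w
}
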