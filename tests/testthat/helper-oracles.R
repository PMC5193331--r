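# Independent oracles used across the test suite.

# Brute-force dynamic-belief posterior by explicit enumeration over all
# change configurations. Changes may occur before every observation after
# the first; each segment's theta is drawn independently and uniformly from
# the grid nodes. Returns the posterior weights over theta at the final
# trial and the predictive probability of X for the next trial.
oracle_dynamic <- function(y, statistic, p_c, resolution) {
  m <- resolution
  g <- (seq_len(m) - 0.5) / m
  if (statistic == "transition") {
    nodes <- expand.grid(gxy = g, gyx = g, KEEP.OUT.ATTRS = FALSE)
    lik_obs <- function(t, node) {
      if (t == 1L) return(rep(0.5, nrow(node)))
      if (y[t - 1L] == 0L) {
        if (y[t] == 1L) node$gyx else 1 - node$gyx
      } else {
        if (y[t] == 0L) node$gxy else 1 - node$gxy
      }
    }
    lik_next <- function(node) {
      if (y[length(y)] == 0L) 1 - node$gyx else node$gxy
    }
  } else if (statistic == "item") {
    nodes <- data.frame(theta = g)
    lik_obs <- function(t, node) if (y[t] == 0L) node$theta else 1 - node$theta
    lik_next <- function(node) node$theta
  } else {
    stop("oracle supports item and transition statistics")
  }
  n_nodes <- nrow(nodes)
  t_len <- length(y)

  # likelihood of observation t at every node
  lik_mat <- vapply(seq_len(t_len), function(t) {
    as.numeric(lik_obs(t, nodes))
  }, numeric(n_nodes))
  if (n_nodes == 1L) lik_mat <- matrix(lik_mat, nrow = 1L)

  configs <- if (t_len == 1L) {
    matrix(FALSE, 1L, 0L)
  } else {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), t_len - 1L)))
  }
  post <- numeric(n_nodes)
  for (ci in seq_len(nrow(configs))) {
    changes <- configs[ci, ]
    p_config <- prod(ifelse(changes, p_c, 1 - p_c))
    # segment boundaries: a new segment starts at t = 1 and wherever a
    # change precedes observation t
    starts <- c(1L, which(changes) + 1L)
    ends <- c(starts[-1L] - 1L, t_len)
    seg_lik <- function(s, e) {
      apply(lik_mat[, s:e, drop = FALSE], 1L, prod)
    }
    contrib <- p_config / n_nodes
    k <- length(starts)
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        contrib <- contrib * mean(seg_lik(starts[j], ends[j]))
      }
    }
    post <- post + contrib * seg_lik(starts[k], ends[k])
  }
  post <- post / sum(post)
  mix <- (1 - p_c) * post + p_c / n_nodes
  list(posterior = post, nodes = nodes,
       p_x_next = sum(as.numeric(lik_next(nodes)) * mix))
}

# Fixed-belief predictive by numerical integration of the posterior-mean
# integral over a fine midpoint grid (independent of the conjugate closed
# form used by the package).
oracle_predictive_item <- function(n_x, n_y, m = 20000L) {
  g <- (seq_len(m) - 0.5) / m
  dens <- g^n_x * (1 - g)^n_y
  sum(g * dens) / sum(dens)
}

# Posterior mode by grid maximization of the unnormalized Beta density.
oracle_beta_mode <- function(shape1, shape2, m = 200001L) {
  g <- seq(0, 1, length.out = m)
  d <- stats::dbeta(g, shape1, shape2)
  g[which.max(d)]
}

# Exhaustive 2-parameter grid minimization of the offset/scale MSE.
oracle_linear_mse <- function(x, z, offsets, scales) {
  best <- Inf
  for (o in offsets) {
    for (s in scales) {
      mse <- mean((z - o - s * x)^2)
      if (mse < best) best <- mse
    }
  }
  best
}
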