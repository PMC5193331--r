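# Fixed-belief conjugate inference: flat Beta prior plus (possibly weighted)
# event counts. The posterior over a frequency is Beta(count + 1, count + 1);
# for transitions it factorizes into two independent Beta distributions, one
# per conditioning symbol. The one-step-ahead prediction is the posterior
# mean of the relevant dimension (Laplace rule of succession).

#' Conjugate Beta posterior from event counts
#'
#' Applies the flat-prior conjugate update: each Beta shape parameter equals
#' the corresponding (possibly leaky-weighted) event count plus one. For the
#' transition statistic the posterior is a product of two independent Beta
#' factors: `theta_x_given_y ~ Beta(n_x_given_y + 1, n_y_given_y + 1)` and
#' `theta_y_given_x ~ Beta(n_y_given_x + 1, n_x_given_x + 1)`.
#'
#' @param counts A one-row tibble of counts as returned by [count_events()]
#'   (or a named numeric vector with the same names).
#' @return A `beta_posterior` object: a tibble with columns `dim`, `shape1`,
#'   `shape2`.
#' @examples
#' beta_posterior(count_events(seq_from_string("XXXXXXX"), "item"))
#' @export
beta_posterior <- function(counts) {
  if (is.data.frame(counts)) counts <- unlist(counts[1, , drop = TRUE])
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) rlang::abort("counts must be nonnegative")
  nm <- names(counts)
  post <- if (all(c("n_x", "n_y") %in% nm)) {
    tibble::tibble(dim = "theta_x",
                   shape1 = counts[["n_x"]] + 1,
                   shape2 = counts[["n_y"]] + 1)
  } else if (all(c("n_rep", "n_alt") %in% nm)) {
    tibble::tibble(dim = "theta_alt",
                   shape1 = counts[["n_alt"]] + 1,
                   shape2 = counts[["n_rep"]] + 1)
  } else if (all(c("n_x_given_y", "n_y_given_x") %in% nm)) {
    tibble::tibble(
      dim = c("theta_x_given_y", "theta_y_given_x"),
      shape1 = c(counts[["n_x_given_y"]], counts[["n_y_given_x"]]) + 1,
      shape2 = c(counts[["n_y_given_y"]], counts[["n_x_given_x"]]) + 1
    )
  } else {
    rlang::abort("unrecognized count names")
  }
  class(post) <- c("beta_posterior", class(post))
  post
}

#' One-step-ahead prediction from a fixed-belief posterior
#'
#' Integrates the next-symbol likelihood over the posterior (the posterior
#' mean of the relevant Beta dimension): the predicted probability of
#' observing X next. For the transition statistic the prediction conditions
#' on the last observed symbol; for the frequency statistics `last_symbol`
#' is ignored (item) or used only to map the alternation probability onto
#' symbols (alternation).
#'
#' @param post A `beta_posterior`.
#' @param last_symbol The most recent symbol (0/1 or "X"/"Y"); required for
#'   the transition and alternation statistics.
#' @return The predictive probability that the next symbol is X.
#' @examples
#' post <- beta_posterior(count_events(seq_from_string("XXXXXXX"), "item"))
#' predictive_fixed(post) # (6 + 1) / (6 + 0 + 2) = 7/8
#' @export
predictive_fixed <- function(post, last_symbol = NULL) {
  mean_of <- function(d) {
    i <- match(d, post$dim)
    post$shape1[i] / (post$shape1[i] + post$shape2[i])
  }
  if ("theta_x" %in% post$dim) return(mean_of("theta_x"))
  if (is.null(last_symbol)) {
    rlang::abort("`last_symbol` is required for this statistic")
  }
  last <- as_symbol_int(last_symbol)
  if ("theta_alt" %in% post$dim) {
    p_alt <- mean_of("theta_alt")
    return(if (last == 0L) 1 - p_alt else p_alt)
  }
  if (last == 0L) 1 - mean_of("theta_y_given_x") else mean_of("theta_x_given_y")
}

# --- Per-trial predictive probabilities for a whole sequence -----------------
# Returns p(y_t | y_{1:t-1}) for every t, using counts over trials < t under
# the observer's scheme; the first prediction is 1/2 (flat prior).
fixed_trace_probs <- function(y, obs) {
  t_len <- length(y)
  integration <- obs$integration
  n <- obs$n
  omega <- obs$omega

  if (obs$statistic == "item") {
    xi <- as.numeric(y == 0L)
    c_all <- running_count(xi, integration, n, omega)
    t_all <- running_count(rep(1, t_len), integration, n, omega)
    c_x <- c(0, c_all[-t_len])   # counts over trials < t
    c_t <- c(0, t_all[-t_len])
    p_x <- (c_x + 1) / (c_t + 2)
    return(ifelse(y == 0L, p_x, 1 - p_x))
  }

  p <- rep(0.5, t_len)
  if (t_len < 3L) return(p)
  from <- y[-t_len]
  to <- y[-1L]
  m <- t_len - 1L # number of pairs
  n_eff <- if (integration == "windowed") n_pairs(integration, n) else n

  if (obs$statistic == "alternation") {
    ai <- as.numeric(from != to)
    c_alt <- running_count(ai, integration, n_eff, omega)
    c_tot <- running_count(rep(1, m), integration, n_eff, omega)
    # prediction at trial t uses pairs 1..t-2
    idx <- 3:t_len
    p_alt <- (c_alt[idx - 2L] + 1) / (c_tot[idx - 2L] + 2)
    observed_alt <- to[idx - 1L] != from[idx - 1L]
    p[idx] <- ifelse(observed_alt, p_alt, 1 - p_alt)
    return(p)
  }

  # transition statistic: four weighted pair counts, leak per pair position
  cxx <- running_count(as.numeric(from == 0L & to == 0L), integration, n_eff,
                       omega)
  cyx <- running_count(as.numeric(from == 0L & to == 1L), integration, n_eff,
                       omega)
  cxy <- running_count(as.numeric(from == 1L & to == 0L), integration, n_eff,
                       omega)
  cyy <- running_count(as.numeric(from == 1L & to == 1L), integration, n_eff,
                       omega)
  idx <- 3:t_len
  j <- idx - 2L # most recent complete pair before trial t
  last <- y[idx - 1L]
  p_x_next <- ifelse(
    last == 0L,
    (cxx[j] + 1) / (cxx[j] + cyx[j] + 2),
    (cxy[j] + 1) / (cxy[j] + cyy[j] + 2)
  )
  p[idx] <- ifelse(y[idx] == 0L, p_x_next, 1 - p_x_next)
  p
}

# Predictive probability of X for the (t+1)-th trial given the whole sequence.
fixed_next_prob <- function(y, obs) {
  t_len <- length(y)
  statistic <- obs$statistic
  counts <- count_events(seq_tbl(y), statistic, obs$integration,
                         n = obs$n, omega = obs$omega)
  predictive_fixed(beta_posterior(counts), last_symbol = y[t_len])
}
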