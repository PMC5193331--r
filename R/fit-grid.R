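# Grid search over the observer's single free parameter: simulate the
# pattern-tree protocol at each parameter value (with sequences shared
# across values, so the MSE curve is noiseless in the parameter), fit the
# offset/scale map, and select the MSE-minimizing value.

#' Theoretical pattern-cell surprise over a parameter grid
#'
#' Simulates the pattern-tree protocol once (the sequences depend only on
#' the seed) and computes the mean surprise per full-length pattern cell for
#' every value of the observer's free parameter. This is the shared
#' workhorse of [fit_observer_grid()], [loo_accuracy()] and
#' [model_recovery()].
#'
#' @param statistic Observer statistic.
#' @param integration `"perfect"`, `"windowed"`, `"leaky"`, or `"dynamic"`.
#' @param param_grid Values of the free parameter (`omega`, `n`, or
#'   `p_change`); ignored (single unparameterized run) for perfect
#'   integration.
#' @inheritParams squires_tree
#' @return A tibble with columns `param`, `condition`, `pattern`,
#'   `mean_surprise`, `n` (occurrences). For perfect integration `param` is
#'   `NA`.
#' @export
simulate_pattern_surprise <- function(statistic, integration,
                                      param_grid = NULL, n_stim = 200,
                                      n_reps = 200,
                                      conditions = c(0.3, 0.5, 0.7),
                                      pattern_len = 5, seed = NULL) {
  if (integration == "perfect") {
    param_grid <- NA_real_
  } else if (is.null(param_grid) || length(param_grid) == 0L) {
    rlang::abort("`param_grid` must be non-empty for parameterized styles")
  }
  seqs <- simulate_condition_sequences(conditions, n_stim, n_reps, seed)
  purrr::map(param_grid, function(par) {
    obs <- observer_from_param(statistic, integration, par)
    cells <- pattern_cells(seqs, obs, pattern_len)
    cells$param <- par
    cells[c("param", "condition", "pattern", "mean_surprise", "n")]
  }) |> dplyr::bind_rows()
}

observer_from_param <- function(statistic, integration, par) {
  switch(integration,
    perfect = observer(statistic, "perfect"),
    leaky = observer(statistic, "leaky", omega = par),
    windowed = observer(statistic, "windowed", n = par),
    dynamic = observer(statistic, "dynamic", p_change = par)
  )
}

#' Fit an observer family to pattern-level data by grid search
#'
#' For every value of the observer's free parameter, simulates theoretical
#' surprise per pattern cell (sequences shared across values), fits the
#' offset/scale map to the data, and records the MSE; the best parameter
#' minimizes MSE (ties broken toward the smallest value). Only full-length
#' pattern cells are fitted. BIC is computed from the best MSE with
#' `k = 2 + ` number of internal parameters.
#'
#' @param data Pattern-level data; see [validate_pattern_data()] for the
#'   schema (columns `condition`, `pattern`, `value`).
#' @inheritParams simulate_pattern_surprise
#' @param weighted If `TRUE`, weight cells by their simulated pattern
#'   frequency (the weighted-MSE robustness variant); default unweighted.
#' @return An `observer_fit` object: list with `statistic`, `integration`,
#'   `grid` (tibble `param`, `mse`, `r2`, `offset`, `scale`), `best_param`,
#'   `best` (the [fit_linear_map()] at the optimum), `n`, `k`, `bic`,
#'   `cells` (per-cell tibble at the optimum).
#' @export
fit_observer_grid <- function(data, statistic, integration = "leaky",
                              param_grid = NULL, n_stim = 200, n_reps = 200,
                              pattern_len = NULL, seed = 1,
                              weighted = FALSE) {
  data <- validate_pattern_data(data)
  if (is.null(pattern_len)) pattern_len <- nchar(data$pattern[1])
  conditions <- sort(unique(data$condition))
  theo <- simulate_pattern_surprise(statistic, integration, param_grid,
                                    n_stim = n_stim, n_reps = n_reps,
                                    conditions = conditions,
                                    pattern_len = pattern_len, seed = seed)
  fit_observer_grid_theo(data, theo, statistic, integration,
                         weighted = weighted)
}

# Fit against precomputed theoretical cells (shared by LOO/model recovery).
fit_observer_grid_theo <- function(data, theo, statistic, integration,
                                   weighted = FALSE, keep = NULL) {
  params <- unique(theo$param)
  fits <- purrr::map(params, function(par) {
    cells <- join_cells(data, theo[is_param(theo$param, par), ], keep = keep)
    w <- if (weighted) cells$n else NULL
    fit_linear_map(cells$mean_surprise, cells$value, weights = w)
  })
  grid <- tibble::tibble(
    param = params,
    mse = vapply(fits, function(f) f$mse, 0),
    r2 = vapply(fits, function(f) f$r2, 0),
    offset = vapply(fits, function(f) f$offset, 0),
    scale = vapply(fits, function(f) f$scale, 0)
  )
  ibest <- which.min(grid$mse) # which.min takes the first (smallest param)
  best <- fits[[ibest]]
  k <- 2L + if (integration == "perfect") 0L else 1L
  cells <- join_cells(data, theo[is_param(theo$param, params[ibest]), ],
                      keep = keep)
  cells$fitted <- best$offset + best$scale * cells$mean_surprise
  structure(
    list(statistic = statistic, integration = integration, grid = grid,
         best_param = params[ibest], best = best, n = best$n, k = k,
         # a zero MSE (exact self-fit) leaves the BIC undefined; flag with NA
         bic = if (best$mse > 0) bic_mse(best$mse, best$n, k) else NA_real_,
         cells = cells, weighted = weighted),
    class = "observer_fit"
  )
}

is_param <- function(x, par) if (is.na(par)) is.na(x) else !is.na(x) & x == par

# Inner join of data cells and theoretical cells with strict key checking.
# match() on a composite key: this sits inside the LOO fold loop.
join_cells <- function(data, theo, keep = NULL) {
  if (!is.null(keep)) data <- data[keep, , drop = FALSE]
  key_d <- paste(data$condition, data$pattern)
  key_t <- paste(theo$condition, theo$pattern)
  idx <- match(key_d, key_t)
  if (anyNA(idx)) {
    rlang::abort(paste0(
      "data cells not produced by the simulation: ",
      paste(utils::head(key_d[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  out <- data
  out$mean_surprise <- theo$mean_surprise[idx]
  out$n <- theo$n[idx]
  out
}

#' @export
print.observer_fit <- function(x, ...) {
  par <- if (is.na(x$best_param)) "none" else format(x$best_param)
  cat(sprintf(
    "<observer_fit> %s / %s: best param = %s, MSE = %.4g, R2 = %.3f, BIC = %.2f (n = %d, k = %d)\n",
    x$statistic, x$integration, par, x$best$mse, x$best$r2, x$bic, x$n, x$k
  ))
  invisible(x)
}

#' Delta-BIC comparison table across fitted observer families
#'
#' @param ... Named `observer_fit` objects (or a single list of them).
#' @return A tibble with one row per model: `model`, `statistic`,
#'   `integration`, `best_param`, `mse`, `r2`, `bic`, `delta_bic` (relative
#'   to the best, i.e. smallest, BIC).
#' @export
bic_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "observer_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(all(vapply(fits, inherits, TRUE, "observer_fit")))
  nm <- names(fits)
  if (is.null(nm)) {
    nm <- vapply(fits, function(f) paste(f$statistic, f$integration,
                                         sep = "-"), "")
  }
  out <- purrr::map2(fits, nm, function(f, name) {
    tibble::tibble(model = name, statistic = f$statistic,
                   integration = f$integration, best_param = f$best_param,
                   mse = f$best$mse, r2 = f$best$r2, bic = f$bic)
  }) |> dplyr::bind_rows()
  out$delta_bic <- out$bic - min(out$bic)
  dplyr::arrange(out, .data$delta_bic)
}
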