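# Leave-one-out predictive accuracy and model recovery. Each fold refits the
# offset, scale, and the observer's internal parameter on n - 1 cells and
# predicts the left-out cell; the error is the unsigned difference. The
# theoretical cell values depend only on the parameter grid and the seed, so
# they are simulated once and shared across folds.

#' Leave-one-out predictive accuracy of an observer family
#'
#' @inheritParams fit_observer_grid
#' @return A `loo_result` object: list with `mean_error`, `sem`,
#'   `per_point` (tibble `condition`, `pattern`, `actual`, `predicted`,
#'   `error`, `best_param`), `statistic`, `integration`.
#' @export
loo_accuracy <- function(data, statistic, integration = "leaky",
                         param_grid = NULL, n_stim = 200, n_reps = 200,
                         pattern_len = NULL, seed = 1, weighted = FALSE) {
  data <- validate_pattern_data(data)
  if (is.null(pattern_len)) pattern_len <- nchar(data$pattern[1])
  theo <- simulate_pattern_surprise(statistic, integration, param_grid,
                                    n_stim = n_stim, n_reps = n_reps,
                                    conditions = sort(unique(data$condition)),
                                    pattern_len = pattern_len, seed = seed)
  loo_accuracy_theo(data, theo, statistic, integration, weighted = weighted)
}

loo_accuracy_theo <- function(data, theo, statistic, integration,
                              weighted = FALSE) {
  n <- nrow(data)
  if (n < 3L) rlang::abort("LOO requires at least 3 cells")
  params <- unique(theo$param)
  # theoretical values aligned to the data rows, one column per parameter
  xmat <- vapply(params, function(par) {
    join_cells(data, theo[is_param(theo$param, par), ])$mean_surprise
  }, numeric(n))
  if (n == 1L) xmat <- matrix(xmat, nrow = 1L)
  z <- data$value
  w_all <- if (weighted) {
    join_cells(data, theo[is_param(theo$param, params[1]), ])$n
  } else {
    rep(1, n)
  }
  folds <- purrr::map(seq_len(n), function(i) {
    fits <- purrr::map(seq_along(params), function(j) {
      fit_linear_map(xmat[-i, j], z[-i], weights = w_all[-i])
    })
    jbest <- which.min(vapply(fits, function(f) f$mse, 0))
    best <- fits[[jbest]]
    pred <- best$offset + best$scale * xmat[i, jbest]
    tibble::tibble(condition = data$condition[i], pattern = data$pattern[i],
                   actual = z[i], predicted = pred,
                   error = abs(pred - z[i]), best_param = params[jbest])
  })
  per_point <- dplyr::bind_rows(folds)
  structure(
    list(mean_error = mean(per_point$error), sem = sem(per_point$error),
         per_point = per_point, statistic = statistic,
         integration = integration),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %s / %s: mean |error| = %.4g (SEM %.4g, %d folds)\n",
    x$statistic, x$integration, x$mean_error, x$sem, nrow(x$per_point)
  ))
  invisible(x)
}

#' Cross-model recovery matrix via leave-one-out prediction
#'
#' Simulates the pattern-cell values of each generating family at its stated
#' parameter, then measures how well every fitting family predicts each
#' simulated dataset with [loo_accuracy()]. A family compared against itself
#' should yield near-zero error (up to Monte-Carlo noise); families learning
#' the same statistic with perfect vs. leaky integration should also recover
#' each other closely; families learning different statistics should not.
#' The procedure is directional, so the matrix need not be symmetric.
#'
#' @param generators Named list of generating families; each element is a
#'   list with `statistic`, `integration`, and `param` (the internal
#'   parameter value, `NA`/absent for perfect integration).
#' @param fitters Named list of fitting families; each element has
#'   `statistic`, `integration`, and `param_grid`. Defaults to the
#'   generators, with a grid around each stated parameter.
#' @inheritParams fit_observer_grid
#' @param data_seed,fit_seed Separate seeds for the generating simulations
#'   and the fitting-side simulations (kept distinct so that self-recovery
#'   reflects true Monte-Carlo error, not shared noise).
#' @return A `recovery_matrix` tibble: `data_model`, `fit_model`,
#'   `mean_error`, `sem`.
#' @export
model_recovery <- function(generators, fitters = NULL, n_stim = 200,
                           n_reps = 200, pattern_len = 5, seed = 1,
                           data_seed = seed, fit_seed = seed + 1000L) {
  stopifnot(is.list(generators), length(generators) >= 1L,
            !is.null(names(generators)))
  if (is.null(fitters)) {
    fitters <- purrr::map(generators, function(g) {
      grid <- if (g$integration == "perfect") NULL else
        default_recovery_grid(g$integration)
      list(statistic = g$statistic, integration = g$integration,
           param_grid = grid)
    })
  }
  stopifnot(!is.null(names(fitters)))

  datasets <- purrr::imap(generators, function(g, nm) {
    par <- if (is.null(g$param)) NA_real_ else g$param
    cells <- simulate_pattern_surprise(
      g$statistic, g$integration,
      param_grid = if (g$integration == "perfect") NULL else par,
      n_stim = n_stim, n_reps = n_reps, pattern_len = pattern_len,
      seed = data_seed
    )
    tibble::tibble(condition = cells$condition, pattern = cells$pattern,
                   value = cells$mean_surprise)
  })

  theos <- purrr::map(fitters, function(f) {
    simulate_pattern_surprise(f$statistic, f$integration, f$param_grid,
                              n_stim = n_stim, n_reps = n_reps,
                              pattern_len = pattern_len, seed = fit_seed)
  })

  out <- purrr::imap(datasets, function(dat, dnm) {
    purrr::imap(theos, function(theo, fnm) {
      f <- fitters[[fnm]]
      loo <- loo_accuracy_theo(dat, theo, f$statistic, f$integration)
      tibble::tibble(data_model = dnm, fit_model = fnm,
                     mean_error = loo$mean_error, sem = loo$sem)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(out, class = c("recovery_matrix", class(out)))
}

default_recovery_grid <- function(integration) {
  switch(integration,
    leaky = c(1:20, seq(22, 40, by = 2)),
    windowed = c(1:20, seq(22, 40, by = 2)),
    dynamic = c(0.005, 0.01, 0.02, 0.05, 0.1, 0.167, 0.3),
    NULL
  )
}
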