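# broom-style tidiers for the fitted objects.

#' Tidy a linear surprise-to-data map
#'
#' @param x A `linear_map` from [fit_linear_map()].
#' @param ... Unused.
#' @return A tibble with one row per term (`offset`, `scale`).
#' @export
tidy.linear_map <- function(x, ...) {
  tibble::tibble(term = c("offset", "scale"),
                 estimate = c(x$offset, x$scale))
}

#' @rdname tidy.linear_map
#' @export
glance.linear_map <- function(x, ...) {
  tibble::tibble(mse = x$mse, r.squared = x$r2, nobs = x$n,
                 degenerate = x$degenerate)
}

#' Tidy an observer grid-search fit
#'
#' `tidy()` returns the MSE-vs-parameter curve (one row per grid value);
#' `glance()` returns a one-row model summary with the best parameter, MSE,
#' R-squared and BIC.
#'
#' @param x An `observer_fit` from [fit_observer_grid()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.observer_fit <- function(x, ...) {
  x$grid
}

#' @rdname tidy.observer_fit
#' @export
glance.observer_fit <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, integration = x$integration,
                 best_param = x$best_param, mse = x$best$mse,
                 r.squared = x$best$r2, bic = x$bic, nobs = x$n, k = x$k)
}

#' Tidy a leave-one-out accuracy result
#'
#' `tidy()` returns the per-fold errors; `glance()` the mean absolute error
#' and its SEM.
#'
#' @param x A `loo_result` from [loo_accuracy()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.loo_result <- function(x, ...) {
  x$per_point
}

#' @rdname tidy.loo_result
#' @export
glance.loo_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, integration = x$integration,
                 mean_error = x$mean_error, sem = x$sem,
                 nobs = nrow(x$per_point))
}
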