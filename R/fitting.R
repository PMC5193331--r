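# Mapping theoretical surprise onto pattern-level data: an offset/scale
# least-squares map, BIC from the MSE, and the input-data schema.

#' Offset/scale least-squares map between model and data
#'
#' Fits `data = offset + scale * model` by (optionally weighted) least
#' squares in closed form, and reports the mean squared error of the
#' residuals and R-squared. If the model values are (numerically) constant
#' the scale is undefined: the fit is flagged `degenerate`, the scale set to
#' 0, the offset to the (weighted) mean of the data, and R-squared to 0 by
#' convention.
#'
#' @param model_values Theoretical values (e.g. mean surprise per pattern).
#' @param data_values Observed values, same length (>= 3).
#' @param weights Optional nonnegative weights (e.g. expected pattern
#'   frequencies for the weighted-MSE robustness variant).
#' @return A `linear_map` object: list with elements `offset`, `scale`,
#'   `mse`, `r2`, `n`, `degenerate`, `fitted`, `residuals`.
#' @examples
#' fit_linear_map(1:5, 3 + 2 * (1:5)) # offset 3, scale 2, mse 0, r2 1
#' @export
fit_linear_map <- function(model_values, data_values, weights = NULL) {
  x <- as.numeric(model_values)
  z <- as.numeric(data_values)
  if (length(x) != length(z)) rlang::abort("vectors must have equal length")
  if (length(x) < 3L) rlang::abort("need at least 3 paired values")
  if (anyNA(x) || anyNA(z)) rlang::abort("missing values in fit inputs")
  w <- if (is.null(weights)) rep(1, length(x)) else as.numeric(weights)
  if (length(w) != length(x) || any(w < 0) || sum(w) <= 0) {
    rlang::abort("`weights` must be nonnegative with positive sum")
  }
  w <- w / sum(w)
  mx <- sum(w * x)
  mz <- sum(w * z)
  vx <- sum(w * (x - mx)^2)
  vz <- sum(w * (z - mz)^2)
  degenerate <- vx < .Machine$double.eps * max(1, mx^2)
  if (degenerate) {
    scale <- 0
    offset <- mz
  } else {
    scale <- sum(w * (x - mx) * (z - mz)) / vx
    offset <- mz - scale * mx
  }
  fitted <- offset + scale * x
  resid <- z - fitted
  mse <- sum(w * resid^2)
  r2 <- if (degenerate || vz <= 0) 0 else 1 - mse / vz
  structure(
    list(offset = offset, scale = scale, mse = mse, r2 = r2,
         n = length(x), degenerate = degenerate, fitted = fitted,
         residuals = resid, weights = w),
    class = "linear_map"
  )
}

#' @export
print.linear_map <- function(x, ...) {
  cat(sprintf(
    "<linear_map> offset = %.4g, scale = %.4g, MSE = %.4g, R2 = %.3f (n = %d)%s\n",
    x$offset, x$scale, x$mse, x$r2, x$n,
    if (x$degenerate) " [degenerate: constant model values]" else ""
  ))
  invisible(x)
}

#' Bayesian Information Criterion from a mean squared error
#'
#' `BIC = n * log(MSE) + k * log(n)` (natural logarithms), the form obtained
#' for least-squares fits with Gaussian residuals. `k` counts the two linear
#' map parameters plus the observer's internal free parameters (0 for
#' perfect integration, 1 otherwise).
#'
#' @param mse Mean squared error (> 0).
#' @param n Number of fitted data points.
#' @param k Total number of free parameters.
#' @return The BIC value.
#' @examples
#' bic_mse(0.47, n = 48, k = 3)
#' @export
bic_mse <- function(mse, n, k) {
  n <- check_count(n, "n")
  k <- check_count(k, "k", min = 0L)
  if (!is.numeric(mse) || length(mse) != 1L || is.na(mse) || mse <= 0) {
    rlang::abort("`mse` must be > 0 (a zero MSE indicates a degenerate perfect fit)")
  }
  n * log(mse) + k * log(n)
}

#' Validate pattern-level data for the fitting layer
#'
#' The expected schema is one row per pattern-by-condition cell: columns
#' `condition` (global P(X), e.g. 0.3/0.5/0.7), `pattern` (a string of 4 or
#' 5 symbols over `{X, Y}` ending in X), and `value` (the measured score).
#'
#' @param data A data frame to validate.
#' @return The data as a tibble (invisibly checked), with `condition`
#'   numeric and `pattern` character.
#' @export
validate_pattern_data <- function(data) {
  if (!is.data.frame(data)) rlang::abort("`data` must be a data frame")
  missing_cols <- setdiff(c("condition", "pattern", "value"), names(data))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out$condition <- as.numeric(out$condition)
  out$pattern <- as.character(out$pattern)
  out$value <- as.numeric(out$value)
  if (nrow(out) == 0L) rlang::abort("`data` has no rows")
  bad <- !grepl("^[XY]{3,4}X$", out$pattern)
  if (any(bad)) {
    rlang::abort(paste0(
      "invalid pattern string(s) (must be 4 or 5 symbols over X/Y ending in X): ",
      paste(utils::head(out$pattern[bad], 5L), collapse = ", ")
    ))
  }
  lens <- unique(nchar(out$pattern))
  if (length(lens) != 1L) {
    rlang::abort("all patterns must have the same length (4 or 5)")
  }
  if (anyNA(out$value) || anyNA(out$condition)) {
    rlang::abort("missing values in `condition` or `value`")
  }
  if (anyDuplicated(out[c("condition", "pattern")]) > 0L) {
    rlang::abort("duplicated condition/pattern cells")
  }
  out
}
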