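# ggplot2 autoplot methods for the result types.

#' Plot a prediction trace
#'
#' @param object A `prediction_trace` from [run_observer()].
#' @param ... Unused.
#' @return A ggplot: surprise over trials, observed symbols on the rug.
#' @export
autoplot.prediction_trace <- function(object, ...) {
  obs <- attr(object, "observer")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$trial, y = .data$surprise)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(ggplot2::aes(color = factor(.data$symbol,
                                                    labels = SYMBOLS)),
                        size = 0.8) +
    ggplot2::labs(x = "trial", y = "surprise (bits)", color = "symbol",
                  title = if (!is.null(obs)) format(obs) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot a surprise tree over stimulus patterns
#'
#' Mean surprise per pattern, by pattern length, one panel per condition —
#' the classic "tree" view of pattern-level sequential effects.
#'
#' @param object A `surprise_tree` from [squires_tree()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surprise_tree <- function(object, ...) {
  df <- tibble::as_tibble(object)
  # connect each pattern to the shorter pattern it extends
  df$parent <- substr(df$pattern, 2L, nchar(df$pattern))
  parents <- df[c("condition", "length", "pattern", "mean_surprise")]
  names(parents) <- c("condition", "parent_length", "parent",
                      "parent_surprise")
  segs <- dplyr::left_join(
    df[df$length > 1L, ],
    dplyr::mutate(parents, length = .data$parent_length + 1L),
    by = c("condition", "length", "parent")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length,
                                   y = .data$mean_surprise)) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$length - 1L, xend = .data$length,
                   y = .data$parent_surprise, yend = .data$mean_surprise),
      color = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "pattern length (stimuli)", y = "mean surprise (bits)") +
    ggplot2::theme_minimal()
}

#' Plot streak-violation effects
#'
#' @param object A `streak_summary` from [huettel_streaks()].
#' @param ... Unused.
#' @return A ggplot: mean surprise against streak length, by outcome,
#'   faceted by streak type.
#' @export
autoplot.streak_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$length, y = .data$mean_surprise,
                               color = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$streak)) +
    ggplot2::labs(x = "streak length (items)", y = "mean surprise (bits)") +
    ggplot2::theme_minimal()
}

#' Plot mean surprise by repetition/alternation code
#'
#' @param object An `ra_summary` from [cho_patterns()].
#' @param ... Unused.
#' @return A ggplot over the 16 codes in canonical order.
#' @export
autoplot.ra_summary <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$code, y = .data$mean_surprise,
                               group = 1)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "repetition/alternation code (last four pairs)",
                  y = "mean surprise (bits)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Plot predictive-entropy curves over alternation frequency
#'
#' @param object An `entropy_curve` from [falk_entropy_curve()].
#' @param ... Unused.
#' @return A ggplot: mean entropy against p(alt), one line per leak value.
#' @export
autoplot.entropy_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$p_alt, y = .data$mean_entropy,
                               color = factor(.data$omega),
                               group = .data$omega)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "alternation probability", y = "mean entropy (bits)",
                  color = "omega") +
    ggplot2::theme_minimal()
}

#' Plot the MSE-vs-parameter curve of a grid-search fit
#'
#' @param object An `observer_fit` from [fit_observer_grid()].
#' @param ... Unused.
#' @return A ggplot with the best parameter marked.
#' @export
autoplot.observer_fit <- function(object, ...) {
  grid <- object$grid
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$param, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_param, linetype = 2,
                        color = "red") +
    ggplot2::labs(x = "free parameter", y = "MSE",
                  title = paste(object$statistic, object$integration,
                                sep = " / ")) +
    ggplot2::theme_minimal()
}

#' Plot a model-recovery error matrix
#'
#' @param object A `recovery_matrix` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot tile map of mean leave-one-out errors.
#' @export
autoplot.recovery_matrix <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fit_model, y = .data$data_model,
                               fill = .data$mean_error)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$mean_error)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "fitting model", y = "generating model",
                  fill = "mean |error|") +
    ggplot2::theme_minimal()
}

#' Plot the posterior heat maps of a change-point demonstration
#'
#' @param object A `changepoint_demo` from [changepoint_demo()].
#' @param ... Unused.
#' @return A ggplot: trial-by-theta posterior marginals per model and
#'   estimated dimension, with the change trial marked.
#' @export
autoplot.changepoint_demo <- function(object, ...) {
  ggplot2::ggplot(object$posteriors,
                  ggplot2::aes(x = .data$trial, y = .data$theta,
                               fill = .data$w)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = object$change_at + 0.5,
                        color = "white", linetype = 2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$dim),
                        cols = ggplot2::vars(.data$model)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "trial", y = "theta", fill = "posterior") +
    ggplot2::theme_minimal()
}
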