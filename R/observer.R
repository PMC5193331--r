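# Observer specification: which statistic is estimated, under which
# integration style, with its single free parameter.

#' Specify an ideal observer
#'
#' An observer is defined by the statistic it estimates (item frequency,
#' alternation frequency, or the two transition probabilities between items),
#' the integration style (perfect, windowed, leaky, or dynamic belief), and
#' the single free parameter of the non-perfect styles: window length `n`,
#' leak time constant `omega`, or a-priori change probability `p_change`.
#' All observers use a flat (uniform) prior on the estimated statistic.
#'
#' @param statistic `"item"`, `"alternation"`, or `"transition"`.
#' @param integration `"perfect"`, `"windowed"`, `"leaky"`, or `"dynamic"`.
#' @param omega Leak time constant, in stimuli (`integration = "leaky"`).
#' @param n Window length, in stimuli (`integration = "windowed"`).
#' @param p_change Per-trial change probability in `[0, 1)`
#'   (`integration = "dynamic"`).
#' @param resolution Grid resolution per dimension for dynamic-belief
#'   inference; defaults to 100 for the 1-D statistics and 50 per dimension
#'   for transitions.
#' @return An object of class `observer`.
#' @examples
#' observer("transition", "leaky", omega = 16)
#' observer("item", "dynamic", p_change = 0.019)
#' @export
observer <- function(statistic = c("transition", "item", "alternation"),
                     integration = c("leaky", "perfect", "windowed",
                                     "dynamic"),
                     omega = NULL, n = NULL, p_change = NULL,
                     resolution = NULL) {
  statistic <- match.arg(statistic)
  integration <- match.arg(integration)
  given <- c(omega = !is.null(omega), n = !is.null(n),
             p_change = !is.null(p_change))
  needed <- switch(integration, perfect = character(0), leaky = "omega",
                   windowed = "n", dynamic = "p_change")
  extra <- setdiff(names(given)[given], needed)
  if (length(extra) > 0L) {
    rlang::abort(sprintf("parameter(s) %s do not apply to %s integration",
                         paste(extra, collapse = ", "), integration))
  }
  if (length(needed) == 1L && !given[[needed]]) {
    rlang::abort(sprintf("%s integration requires `%s`", integration, needed))
  }
  if (!is.null(omega) && (!is.numeric(omega) || length(omega) != 1L ||
                          omega <= 0)) {
    rlang::abort("`omega` must be a single positive number")
  }
  if (!is.null(n)) n <- check_count(n, "n")
  if (!is.null(p_change)) {
    p_change <- check_probability(p_change, "p_change")
    if (p_change >= 1) rlang::abort("`p_change` must be < 1")
  }
  if (integration == "dynamic" && is.null(resolution)) {
    resolution <- if (statistic == "transition") 50L else 100L
  }
  if (!is.null(resolution)) resolution <- check_count(resolution,
                                                      "resolution", min = 2L)
  structure(
    list(statistic = statistic, integration = integration, omega = omega,
         n = n, p_change = p_change, resolution = resolution),
    class = "observer"
  )
}

#' @export
print.observer <- function(x, ...) {
  par <- switch(x$integration,
    perfect = "no free parameter",
    leaky = sprintf("omega = %g stimuli", x$omega),
    windowed = sprintf("window n = %d stimuli", x$n),
    dynamic = sprintf("p_change = %g, grid %d per dim", x$p_change,
                      x$resolution)
  )
  cat(sprintf("<observer> %s statistic, %s integration (%s)\n",
              x$statistic, x$integration, par))
  invisible(x)
}

#' @export
format.observer <- function(x, ...) {
  par <- switch(x$integration, perfect = "", leaky = sprintf("(%g)", x$omega),
                windowed = sprintf("(%d)", x$n),
                dynamic = sprintf("(%g)", x$p_change))
  paste0(x$statistic, "-", x$integration, par)
}

# Number of internal free parameters: 0 for perfect, 1 otherwise.
observer_k <- function(x) if (x$integration == "perfect") 0L else 1L
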