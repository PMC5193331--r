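# Information-theoretic readouts of predictions, in bits.

#' Shannon surprise of an observed probability
#'
#' `-log2(p)`: 1 bit for p = 1/2, 0 bits for a certain event. Probabilities
#' are floored at machine epsilon before taking the log so that degenerate
#' traces never produce infinities; conjugate predictives never reach 0
#' exactly, so the floor is inert in normal use.
#'
#' @param p Predicted probability(ies) of the observed symbol, in (0, 1].
#' @return Surprise in bits (same length as `p`).
#' @examples
#' surprise(c(1, 0.5, 0.25)) # 0, 1, 2 bits
#' @export
surprise <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("`p` must be in [0, 1]")
  }
  if (any(p <= 0, na.rm = TRUE)) {
    rlang::abort("surprise is undefined for p <= 0")
  }
  -log2(pmax(p, .Machine$double.eps))
}

#' Binary Shannon entropy
#'
#' `H(p) = -p log2(p) - (1-p) log2(1-p)`, with `0 * log(0) := 0`. Symmetric
#' in `p <-> 1 - p`, maximal (1 bit) at p = 0.5. Used as the model's measure
#' of the perceived randomness of the next outcome.
#'
#' @param p Probability(ies) in \[0, 1\].
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(c(0, 0.5, 0.25))
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    rlang::abort("`p` must be in [0, 1]")
  }
  term <- function(q) ifelse(q <= 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}
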