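# Symbols are stored as integers: 0 = "X", 1 = "Y".

SYMBOLS <- c("X", "Y")

#' Build a sequence tibble from a vector of symbols
#'
#' Sequences are represented as tibbles with a `trial` index and an integer
#' `symbol` column (0 = X, 1 = Y). All observers and experiment pipelines in
#' the package consume this form.
#'
#' @param symbols Integer vector of 0/1, logical vector, or character vector
#'   over `"X"`/`"Y"`.
#' @return A tibble with columns `trial` and `symbol`.
#' @examples
#' seq_tbl(c("X", "Y", "X"))
#' seq_tbl(c(0, 1, 1))
#' @export
seq_tbl <- function(symbols) {
  tibble::tibble(trial = seq_along(symbols), symbol = as_symbol_int(symbols))
}

#' Parse a symbol string into a sequence tibble
#'
#' @param string A single string over the alphabet `{X, Y}`, e.g. `"XYXYY"`.
#' @return A tibble with columns `trial` and `symbol`.
#' @examples
#' seq_from_string("XYXYY")
#' @export
seq_from_string <- function(string) {
  stopifnot(is.character(string), length(string) == 1L)
  chars <- strsplit(string, "")[[1]]
  if (!all(chars %in% SYMBOLS)) {
    rlang::abort("sequence strings may only contain 'X' and 'Y'")
  }
  seq_tbl(chars)
}

#' Render a sequence as a symbol string
#'
#' @param data A sequence tibble (see [seq_tbl()]).
#' @return A single string over `{X, Y}`.
#' @examples
#' seq_to_string(seq_tbl(c(0, 1, 0)))
#' @export
seq_to_string <- function(data) {
  paste(SYMBOLS[symbols_of(data) + 1L], collapse = "")
}

# Coerce any accepted symbol encoding to integer 0/1.
as_symbol_int <- function(x) {
  if (is.character(x)) {
    if (!all(x %in% SYMBOLS)) rlang::abort("symbols must be 'X' or 'Y'")
    return(ifelse(x == "Y", 1L, 0L))
  }
  x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    rlang::abort("symbols must be 0/1 (or 'X'/'Y')")
  }
  x
}

# Extract the integer symbol vector from a sequence tibble or raw vector.
symbols_of <- function(data) {
  if (is.data.frame(data)) {
    if (!"symbol" %in% names(data)) {
      rlang::abort("sequence data must have a 'symbol' column")
    }
    x <- data$symbol
  } else {
    x <- data
  }
  if (length(x) < 1L) rlang::abort("sequences must have length >= 1")
  as_symbol_int(x)
}

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    rlang::abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(p)
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
      n != round(n)) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(n)
}

# Standard error of the mean, NA-safe for n = 1.
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
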