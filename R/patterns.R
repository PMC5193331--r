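# Recent-history pattern encodings: last-k symbol windows, repetition/
# alternation codes over the last five stimuli, and streak descriptors.

#' Last-k symbol pattern at a position
#'
#' @param data A sequence tibble.
#' @param t Trial index at which the pattern terminates.
#' @param k Pattern length (1 to 5).
#' @return A string of `k` symbols, positions `t - k + 1` to `t`.
#' @examples
#' pattern_lastk(seq_from_string("XYXYY"), t = 5, k = 3)
#' @export
pattern_lastk <- function(data, t, k = 5) {
  y <- symbols_of(data)
  k <- check_count(k, "k")
  if (k > 5L) rlang::abort("`k` must be between 1 and 5")
  t <- check_count(t, "t")
  if (t > length(y) || t < k) rlang::abort("`t` out of range for pattern")
  paste(SYMBOLS[y[(t - k + 1L):t] + 1L], collapse = "")
}

#' Repetition/alternation code of the last five stimuli
#'
#' The four consecutive pairs within the window of five stimuli ending at `t`
#' are each coded R (repetition) or A (alternation), most recent pair last.
#' Enumerating all 2^5 windows yields 2^4 = 16 distinct codes.
#'
#' @inheritParams pattern_lastk
#' @return A 4-letter string over `{R, A}`, e.g. `"AAAR"` for `...XYXYY`.
#' @examples
#' ra_code(seq_from_string("XYXYY"), t = 5)
#' @export
ra_code <- function(data, t) {
  y <- symbols_of(data)
  t <- check_count(t, "t")
  if (t < 5L || t > length(y)) rlang::abort("`t` must be in [5, length]")
  win <- y[(t - 4L):t]
  paste(c("R", "A")[as.integer(diff(win) != 0L) + 1L], collapse = "")
}

#' Streak descriptor at a position
#'
#' Finds the maximal run of consistent repetitions or alternations
#' immediately preceding trial `t` and reports whether the symbol at `t`
#' continues or violates it. Streak length is counted in items (a streak of
#' four repeated items contains three repetition pairs) and capped at
#' `max_len`.
#'
#' @inheritParams pattern_lastk
#' @param max_len Cap on the reported streak length.
#' @return A one-row tibble with columns `streak` ("repetition"/
#'   "alternation"), `length`, `outcome` ("continued"/"violated").
#' @examples
#' streak_descriptor(seq_from_string("XXXXY"), t = 5) # repetition, 4, violated
#' @export
streak_descriptor <- function(data, t, max_len = 8) {
  y <- symbols_of(data)
  t <- check_count(t, "t")
  if (t < 3L || t > length(y)) rlang::abort("`t` must be in [3, length]")
  a <- as.integer(diff(y[seq_len(t)]) != 0L) # pair types up to pair (t-1, t)
  prev <- a[seq_len(t - 2L)]                 # pairs strictly before trial t
  type <- prev[t - 2L]
  run <- 1L
  while (t - 2L - run >= 1L && prev[t - 2L - run] == type) run <- run + 1L
  len <- min(run + 1L, as.integer(max_len))  # items = consistent pairs + 1
  tibble::tibble(
    streak = c("repetition", "alternation")[type + 1L],
    length = len,
    outcome = if (a[t - 1L] == type) "continued" else "violated"
  )
}

# Canonical display/reporting order of the 16 R/A codes: the eight codes
# ending in a repetition first, then the eight ending in an alternation,
# earlier pairs cycling fastest with A treated as the discrepant letter.
RA_LEVELS <- c(
  "RRRR", "ARRR", "RARR", "AARR", "RRAR", "ARAR", "RAAR", "AAAR",
  "RRRA", "ARRA", "RARA", "AARA", "RRAA", "ARAA", "RAAA", "AAAA"
)

# Vectorized helpers used by the experiment pipelines -------------------------

# Integer key of the last-k window ending at each eligible t (t >= k);
# returns NA elsewhere. Key = sum over window of symbol * 2^(k - pos).
lastk_keys <- function(y, k) {
  t_len <- length(y)
  keys <- rep(NA_integer_, t_len)
  if (t_len < k) return(keys)
  acc <- integer(t_len - k + 1L)
  for (j in seq_len(k)) {
    acc <- acc + y[j:(t_len - k + j)] * 2L^(k - j)
  }
  keys[k:t_len] <- acc
  keys
}

key_to_pattern <- function(key, k) {
  key <- as.numeric(key)
  bits <- vapply(seq_len(k), function(j) (key %/% 2^(k - j)) %% 2,
                 numeric(length(key)))
  if (length(key) == 1L) bits <- matrix(bits, nrow = 1L)
  apply(bits, 1L, function(b) paste(SYMBOLS[b + 1L], collapse = ""))
}

# R/A code (as index into RA_LEVELS) of the window ending at each t >= 5.
ra_keys <- function(y) {
  a <- c(NA_integer_, as.integer(diff(y) != 0L)) # a[t] = type of pair (t-1, t)
  t_len <- length(y)
  keys <- rep(NA_integer_, t_len)
  if (t_len < 5L) return(keys)
  idx <- 5:t_len
  code <- a[idx - 3L] * 8L + a[idx - 2L] * 4L + a[idx - 1L] * 2L + a[idx]
  keys[idx] <- code
  keys
}

ra_key_to_code <- function(key) {
  bits <- cbind(key %/% 8L %% 2L, key %/% 4L %% 2L, key %/% 2L %% 2L,
                key %% 2L)
  apply(bits, 1L, function(b) paste(c("R", "A")[b + 1L], collapse = ""))
}

# Streak classification of every trial t >= 3 of a sequence: type of the
# maximal consistent run of pairs before t, its length in items (capped),
# and whether trial t continued it.
streak_table <- function(y, max_len = 8L) {
  t_len <- length(y)
  if (t_len < 3L) {
    return(tibble::tibble(trial = integer(), streak = character(),
                          length = integer(), outcome = character()))
  }
  a <- as.integer(diff(y) != 0L)          # a[i] = type of pair (i, i+1)
  runlen <- sequence(rle(a)$lengths)      # run length of a ending at i
  idx <- 3:t_len                          # trials with >= 1 preceding pair
  type <- a[idx - 2L]                     # type of last pair before t
  len <- pmin(runlen[idx - 2L] + 1L, as.integer(max_len))
  continued <- a[idx - 1L] == type
  tibble::tibble(
    trial = idx,
    streak = c("repetition", "alternation")[type + 1L],
    length = len,
    outcome = ifelse(continued, "continued", "violated")
  )
}
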