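# Plain-text I/O: sequences as symbol strings or CSV, pattern-level data
# CSV for the fitting layer, and JSON sidecars recording run provenance.

#' Read pattern-level data from CSV
#'
#' Expects the fitting-layer schema: columns `condition` (global P(X)),
#' `pattern` (4 or 5 symbols over `{X, Y}` ending in X), `value`.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble (see [validate_pattern_data()]).
#' @export
read_pattern_data <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_pattern_data(df)
}

#' Write a sequence to CSV
#'
#' Columns `trial`, `symbol` (0 = X, 1 = Y), and `change` when present.
#'
#' @param data A sequence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequence_csv <- function(data, path) {
  keep <- intersect(c("trial", "symbol", "change"), names(data))
  utils::write.csv(as.data.frame(data)[keep], path, row.names = FALSE)
  invisible(path)
}

#' Read a sequence from CSV
#'
#' @param path Path to a CSV with a `symbol` column (0/1 or X/Y).
#' @return A sequence tibble.
#' @export
read_sequence_csv <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- seq_tbl(df$symbol)
  if ("change" %in% names(df)) out$change <- as.logical(df$change)
  out
}

# Provenance sidecar written next to experiment CSVs by the CLI.
run_sidecar <- function(obs, seed, extra = list()) {
  c(list(
    observer = list(statistic = obs$statistic,
                    integration = obs$integration,
                    omega = obs$omega, n = obs$n, p_change = obs$p_change,
                    resolution = obs$resolution),
    seed = seed,
    package_version = as.character(utils::packageVersion("seqsurprise")),
    r_version = R.version.string
  ), extra)
}
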