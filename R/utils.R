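#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from a single integer master seed.
#' Independent stages draw from streams obtained by hashing the master seed
#' with a small stage offset; the result always stays below 2^31 - 1 so it is
#' a valid R integer seed.
#'
#' @param seed master integer seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed for `set.seed()`.
#' @export
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  # Lehmer-style mixing; constants are the classic MINSTD multiplier
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + 12345 + 104729 * as.numeric(stream)) %% m
  as.integer(max(1, s))
}

#' Write a data frame as a plain TSV
#'
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plain TSV written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# clamp probabilities away from 0 so that log() is finite
clamp_p <- function(p) pmax(p, .Machine$double.xmin)

`%||%` <- function(a, b) if (is.null(a)) b else a
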