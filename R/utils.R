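#' Derive a reproducible sub-seed for a named random stream
#'
#' Each simulated output object (exon counts, intron counts, reads, UTR
#' lengths, resampling replicates, ...) draws from its own stream derived from
#' the master seed, so adding one output never perturbs the others.
#'
#' @param seed master integer seed.
#' @param name character name of the stream.
#' @return an integer in [1, 2^31 - 2] suitable for `set.seed()`.
#' @export
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  s <- (abs(as.numeric(seed)) %% 2147000000 + h * 1009) %% 2147483646
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV
#'
#' Plain TSV writer used for all tabular outputs (no quoting, no row names).
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_plain()]
#' @param path input path.
#' @return data frame.
#' @export
read_tsv_plain <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
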