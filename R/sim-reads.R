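#' Default library-prep adapter sequences
#'
#' The 3' adapter's invariant portion (the chemistry marks and the four
#' random-sequence positions at its 5' end are not part of the invariant) and
#' a 5' adapter whose four random 3' positions end up at the start of each
#' read. Used as generator defaults; the quantifier takes adapters as
#' arguments.
#' @name adapters
#' @export
default_adapter3 <- function() "TCGTATGCCGTCTTCTGCTTG"

#' @rdname adapters
#' @export
default_adapter5 <- function() "GTTCAGAGTTCTACAGTCCGACGATC"

rand_nt <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate small-RNA sequencing reads
#'
#' Each read is 4 random nt + the mature miRNA sequence + 4 random nt + the
#' 3'-adapter invariant, truncated to the configured read length. Species are
#' drawn multinomially: biological miRNAs in proportion to their abundance in
#' the requested group (scaled by the per-group fold changes in the config's
#' miRNA table) and spike-in species at the configured fixed total
#' proportion. All bases are Q37 except that a configurable fraction of reads
#' carries one Q20 base, to exercise the Q30 quality filter downstream.
#'
#' @param config a [sim_config()].
#' @param adapter3 invariant 3'-adapter sequence appended after the insert.
#' @param adapter5 5' adapter (its randomized 3' tail is what contributes the
#'   4 random leading nucleotides; accepted for interface completeness).
#' @param n_reads number of reads to simulate.
#' @param group group label whose abundances are used (default: control).
#' @param seed optional seed overriding the config's "reads" stream.
#' @return list with `reads` (data frame: read_id, sequence, quality) and
#'   `true_counts` (data frame: mirna_id, family, is_spike_in, count).
#' @export
simulate_small_rna_reads <- function(config,
                                     adapter3 = default_adapter3(),
                                     adapter5 = default_adapter5(),
                                     n_reads,
                                     group = NULL,
                                     seed = NULL) {
  cfg <- validate_sim_config(config)
  group <- group %||% cfg$groups[1L]
  stopifnot(group %in% cfg$groups)
  fam <- cfg$mirna_families
  bio <- fam[!fam$is_spike_in, ]
  spk <- fam[fam$is_spike_in, ]
  ab <- bio$baseline
  if (group != cfg$groups[1L]) ab <- ab * bio[[paste0("fc_", group)]]
  p_bio <- (1 - cfg$spikein_proportion) * ab / sum(ab)
  p_spk <- if (nrow(spk)) rep(cfg$spikein_proportion / nrow(spk), nrow(spk))
           else numeric(0)
  species <- rbind(bio[, c("mirna_id", "family", "is_spike_in", "sequence")],
                   spk[, c("mirna_id", "family", "is_spike_in", "sequence")])
  prob <- c(p_bio, p_spk)

  set.seed(seed %||% stream_seed(cfg$seed, paste0("reads_", group)))
  if (n_reads == 0L) {
    return(list(reads = data.frame(read_id = character(0),
                                   sequence = character(0),
                                   quality = character(0),
                                   stringsAsFactors = FALSE),
                true_counts = cbind(species[, 1:3],
                                    count = integer(nrow(species)))))
  }
  counts <- as.integer(stats::rmultinom(1L, n_reads, prob))
  which_sp <- rep(seq_len(nrow(species)), counts)
  which_sp <- sample(which_sp)  # shuffle read order
  mature <- chartr("U", "T", species$sequence)[which_sp]
  full <- paste0(rand_nt(n_reads, 4L), mature, rand_nt(n_reads, 4L), adapter3)
  sequence <- substr(full, 1L, cfg$read_length)
  len <- nchar(sequence)

  qual <- strrep(rawToChar(as.raw(37L + 33L)), len)
  n_bad <- round(cfg$subq30_read_fraction * n_reads)
  if (n_bad > 0) {
    bad <- sample.int(n_reads, n_bad)
    pos <- 1L + floor(stats::runif(n_bad) * len[bad])
    substr(qual[bad], pos, pos) <- rawToChar(as.raw(20L + 33L))
  }
  list(reads = data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
                          sequence = sequence, quality = qual,
                          stringsAsFactors = FALSE),
       true_counts = cbind(species[, c("mirna_id", "family", "is_spike_in")],
                           count = counts))
}

#' Read / write FASTQ (Phred+33) as a read data frame
#'
#' Thin wrappers over Biostrings' FASTQ support, exchanging the plain
#' data-frame read representation used throughout the small-RNA module.
#' @param path FASTQ file path.
#' @return `read_fastq`: data frame with read_id, sequence, quality.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = names(x) %||% sprintf("read%06d", seq_along(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data frame with columns read_id, sequence, quality.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
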