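## Small-RNA quantification: quality filter -> adapter trim -> exact-prefix
## dictionary match -> spike-in removal -> CPM.

phred_ok_fraction <- function(quality, min_q) {
  n <- nchar(quality)
  if (length(quality) == 0L) return(numeric(0))
  ints <- as.integer(charToRaw(paste(quality, collapse = ""))) - 33L
  grp <- rep.int(seq_along(quality), n)
  ok <- rowsum((ints >= min_q) + 0, grp, reorder = FALSE)[, 1L]
  ok / n
}

#' Quality-filter FASTQ reads
#'
#' Retains reads in which at least `min_frac` of bases have Phred quality
#' >= `min_q` (inclusive). The defaults (Q30, all bases) reproduce the usual
#' small-RNA "-q 30 -p 100" filter.
#'
#' @param reads data frame with columns read_id, sequence, quality
#'   (Phred+33), as returned by [read_fastq()] or the generator.
#' @param min_q minimum per-base quality (default 30).
#' @param min_frac minimum fraction of bases meeting `min_q` (default 1).
#' @return the retained subset, with attribute `n_filtered`.
#' @export
quality_filter <- function(reads, min_q = 30L, min_frac = 1.0) {
  stopifnot(all(c("sequence", "quality") %in% names(reads)))
  bad_len <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad_len))
    stop("malformed FASTQ record at index ", which(bad_len)[1L],
         ": sequence and quality lengths differ")
  keep <- phred_ok_fraction(reads$quality, min_q) >= min_frac
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' Trim the 3' adapter and randomized flanking nucleotides
#'
#' Locates the leftmost exact match of the first 8 nt of the 3'-adapter
#' invariant, removes it and everything after, then strips `n_random_5p`
#' leading and `n_random_3p` trailing randomized nucleotides (introduced by
#' the adapters' random-sequence positions). Reads without an adapter hit,
#' or whose post-adapter-removal length is below
#' `n_random_5p + n_random_3p + 16`, are dropped and tallied rather than
#' raised.
#'
#' @param reads read data frame (read_id, sequence, quality).
#' @param adapter3_invariant invariant portion of the 3' adapter (>= 8 nt).
#' @param n_random_5p,n_random_3p randomized positions to strip from each end.
#' @return data frame of trimmed reads (read_id, sequence) with attributes
#'   `n_no_adapter` and `n_too_short`.
#' @export
trim_adapters <- function(reads, adapter3_invariant = default_adapter3(),
                          n_random_5p = 4L, n_random_3p = 4L) {
  if (nchar(adapter3_invariant) < 8L)
    stop("adapter invariant must be >= 8 nt")
  probe <- toupper(substr(adapter3_invariant, 1L, 8L))
  pos <- regexpr(probe, toupper(reads$sequence), fixed = TRUE)
  insert_len <- ifelse(pos > 0L, pos - 1L, NA_integer_)
  min_len <- n_random_5p + n_random_3p + 16L
  no_adapter <- pos < 0L
  too_short <- !no_adapter & insert_len < min_len
  keep <- !no_adapter & !too_short
  out <- data.frame(
    read_id = reads$read_id[keep],
    sequence = substr(reads$sequence[keep], n_random_5p + 1L,
                      insert_len[keep] - n_random_3p),
    stringsAsFactors = FALSE)
  attr(out, "n_no_adapter") <- sum(no_adapter)
  attr(out, "n_too_short") <- sum(too_short)
  out
}

#' Load and validate a mature miRNA dictionary
#'
#' Normalizes sequences (uppercase, U -> T), checks alphabet and uniqueness,
#' and enforces the k-prefix collision policy: two entries with different
#' full sequences but identical first-k prefixes are an error (they would be
#' indistinguishable to exact-prefix matching); entries with identical full
#' sequences (paralogs producing the same mature miRNA) are an error unless
#' `collapse_identical = TRUE`, in which case they are collapsed into one
#' entry whose id lists all members separated by ";". Silent double-counting
#' is never an option.
#'
#' @param dict data frame with columns mirna_id, sequence and optionally
#'   family, is_spike_in, is_size_standard; or a path to such a TSV.
#' @param k prefix length that will be used for matching.
#' @param collapse_identical collapse full-sequence duplicates into one entry.
#' @return validated dictionary data frame of class `mirna_dictionary`.
#' @export
load_mirna_dictionary <- function(dict, k = 19L, collapse_identical = FALSE) {
  if (is.character(dict) && length(dict) == 1L) dict <- read_tsv_plain(dict)
  stopifnot(all(c("mirna_id", "sequence") %in% names(dict)))
  dict$family <- dict$family %||% dict$mirna_id
  dict$is_spike_in <- as.logical(dict$is_spike_in %||% FALSE)
  dict$is_size_standard <- as.logical(dict$is_size_standard %||% FALSE)
  dict$sequence <- chartr("U", "T", toupper(dict$sequence))
  if (any(grepl("[^ACGT]", dict$sequence)))
    stop("dictionary sequences must be over {A,C,G,T/U}")
  if (anyDuplicated(dict$mirna_id)) stop("dictionary ids must be unique")
  if (any(nchar(dict$sequence) < k))
    stop("all dictionary sequences must be >= prefix length k = ", k)
  if (anyDuplicated(dict$sequence)) {
    if (!collapse_identical)
      stop("identical mature sequences in dictionary (",
           paste(dict$mirna_id[duplicated(dict$sequence) |
                               duplicated(dict$sequence, fromLast = TRUE)],
                 collapse = ", "),
           "); set collapse_identical = TRUE to merge them")
    agg <- split(seq_len(nrow(dict)), dict$sequence)
    dict <- do.call(rbind, lapply(agg, function(i) {
      d <- dict[i[1L], , drop = FALSE]
      d$mirna_id <- paste(dict$mirna_id[i], collapse = ";")
      d$is_spike_in <- any(dict$is_spike_in[i])
      d$is_size_standard <- any(dict$is_size_standard[i])
      d
    }))
    rownames(dict) <- NULL
  }
  pre <- substr(dict$sequence, 1L, k)
  if (anyDuplicated(pre)) {
    clash <- pre[duplicated(pre)][1L]
    stop("ambiguous dictionary: entries ",
         paste(dict$mirna_id[pre == clash], collapse = ", "),
         " share the same first-", k, " nt prefix but differ in full sequence")
  }
  attr(dict, "k") <- as.integer(k)
  class(dict) <- c("mirna_dictionary", "data.frame")
  dict
}

#' Count trimmed reads against a miRNA dictionary by exact prefix match
#'
#' A read is assigned to the unique dictionary entry whose first `k`
#' nucleotides equal the read's first `k` nucleotides (no mismatches).
#' Reads matching spike-in or size-standard entries are removed from the
#' biological counts but tallied; reads matching nothing are unmatched.
#'
#' @param reads trimmed read data frame (column `sequence`) or character
#'   vector of sequences.
#' @param dict a [load_mirna_dictionary()] result.
#' @param k prefix length; defaults to the dictionary's validated k.
#' @return list of class `mirna_counts`: `counts` (named integer vector over
#'   biological dictionary entries) and `totals` (reads_in, matched,
#'   removed_spike, unmatched).
#' @export
match_prefix <- function(reads, dict, k = attr(dict, "k")) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- chartr("U", "T", toupper(seqs))
  hit <- match(substr(seqs, 1L, k), substr(dict$sequence, 1L, k))
  hit[!is.na(hit) & nchar(seqs) < k] <- NA  # short reads cannot match
  removed <- !is.na(hit) & (dict$is_spike_in[hit] | dict$is_size_standard[hit])
  bio <- dict$mirna_id[!dict$is_spike_in & !dict$is_size_standard]
  tab <- table(factor(dict$mirna_id[hit[!is.na(hit) & !removed]], levels = bio))
  counts <- stats::setNames(as.integer(tab), bio)
  out <- list(counts = counts,
              totals = list(reads_in = length(seqs),
                            matched = sum(!is.na(hit) & !removed),
                            removed_spike = sum(removed),
                            unmatched = sum(is.na(hit))))
  class(out) <- "mirna_counts"
  out
}

#' One-sample small-RNA quantification pipeline
#'
#' Quality filter, adapter trim, exact-prefix match, with full read
#' accounting: `matched + unmatched + removed_spike + q_filtered = reads_in`
#' (adapter-less and too-short reads are part of `unmatched`, and also
#' reported separately).
#'
#' @inheritParams quality_filter
#' @inheritParams trim_adapters
#' @param dict a [load_mirna_dictionary()] result.
#' @param k prefix length (19 or 18 by cohort convention; configurable).
#' @return `mirna_counts` with extended totals.
#' @export
quantify_mirnas <- function(reads, dict, k = attr(dict, "k"),
                            min_q = 30L, min_frac = 1.0,
                            adapter3_invariant = default_adapter3(),
                            n_random_5p = 4L, n_random_3p = 4L) {
  n_in <- nrow(reads)
  qf <- quality_filter(reads, min_q = min_q, min_frac = min_frac)
  tr <- trim_adapters(qf, adapter3_invariant, n_random_5p, n_random_3p)
  mc <- match_prefix(tr, dict, k)
  dropped <- attr(tr, "n_no_adapter") + attr(tr, "n_too_short")
  mc$totals <- list(reads_in = n_in,
                    q_filtered = attr(qf, "n_filtered"),
                    adapter_dropped = dropped,
                    matched = mc$totals$matched,
                    removed_spike = mc$totals$removed_spike,
                    unmatched = mc$totals$unmatched + dropped)
  mc
}

#' Counts-per-million normalization for miRNA counts
#'
#' Each count is divided by its sample's size factor; the normalized counts
#' are then expressed as a proportion of the sample's normalized total and
#' multiplied by 1e6, so every sample's CPM column sums to one million.
#'
#' @param counts miRNA x sample matrix of raw counts (or a single
#'   `mirna_counts` object).
#' @param size_factors positive per-sample factors (default all 1).
#' @return CPM matrix of the same shape.
#' @export
mirna_cpm <- function(counts, size_factors = NULL) {
  if (inherits(counts, "mirna_counts"))
    counts <- matrix(counts$counts, ncol = 1L,
                     dimnames = list(names(counts$counts), "sample1"))
  size_factors <- size_factors %||% rep(1, ncol(counts))
  if (any(size_factors <= 0)) stop("size factors must be > 0")
  norm <- sweep(counts, 2L, size_factors, "/")
  tot <- colSums(norm)
  if (any(tot == 0)) stop("zero-total sample: CPM undefined")
  sweep(norm, 2L, tot, "/") * 1e6
}
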