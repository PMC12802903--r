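## Merged exon/intron annotation and a toy union-mode read counter.
##
## Coordinate convention: GTF is 1-based inclusive and converted at the I/O
## boundary; every interval exposed by this module is 0-based half-open.

#' Read gene models (exon structures) from a GTF file
#'
#' Keeps `exon` features and their gene_id / transcript_id attributes.
#'
#' @param path GTF file path.
#' @return data frame of exons with columns gene_id, transcript_id, chrom,
#'   strand, start, end (0-based half-open), class `gene_models`.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  out <- data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Merge transcripts into per-gene exon-union and intron-union interval sets
#'
#' For each gene, the exon union is the interval union of all exons across
#' all transcripts; the intron union is the gene span (minimum exon start to
#' maximum exon end across transcripts) minus the exon union, i.e. all
#' introns combined into a single annotation. Single-exon genes get an empty
#' intron union.
#'
#' @param models exon table as returned by [read_gtf_models()] (columns
#'   gene_id, chrom, strand, start, end; 0-based half-open).
#' @return data frame with columns gene_id, chrom, strand, kind
#'   (`exon_union` / `intron_union`), start, end; sorted, disjoint intervals
#'   per (gene, kind).
#' @export
merge_gene_intervals <- function(models) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                names(models)))
  chrom_per_gene <- tapply(models$chrom, models$gene_id,
                           function(x) length(unique(x)))
  strand_per_gene <- tapply(models$strand, models$gene_id,
                            function(x) length(unique(x)))
  if (any(chrom_per_gene > 1L) || any(strand_per_gene > 1L))
    stop("model error: a gene's exons span multiple chromosomes or strands")
  gr <- GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand, gene_id = models$gene_id)
  pieces <- lapply(split(gr, gr$gene_id), function(g) {
    exon <- GenomicRanges::reduce(g, ignore.strand = TRUE)
    span <- range(GenomicRanges::ranges(exon))
    intron <- IRanges::setdiff(span, GenomicRanges::ranges(exon))
    mk <- function(r, kind) {
      if (length(r) == 0L)
        return(data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), kind = character(0),
                          start = integer(0), end = integer(0)))
      data.frame(gene_id = g$gene_id[1L],
                 chrom = as.character(GenomicRanges::seqnames(g))[1L],
                 strand = as.character(GenomicRanges::strand(g))[1L],
                 kind = kind,
                 start = IRanges::start(r) - 1L, end = IRanges::end(r),
                 stringsAsFactors = FALSE)
    }
    rbind(mk(GenomicRanges::ranges(exon), "exon_union"),
          mk(intron, "intron_union"))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

cigar_to_blocks <- function(pos0, cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(toks) == 0L) stop("unparseable CIGAR: ", cigar)
  lens <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  starts <- integer(0); ends <- integer(0)
  cur_start <- pos0; cur <- pos0
  open <- FALSE
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "D", "=", "X")) {
      if (!open) { cur_start <- cur; open <- TRUE }
      cur <- cur + lens[i]
    } else if (op[i] == "N") {
      if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
      cur <- cur + lens[i]; open <- FALSE
    }
    # I, S, H, P consume no reference
  }
  if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur) }
  list(start = starts, end = ends)
}

#' Read a minimal single-end SAM subset as alignment records
#'
#' Parses QNAME, FLAG (strand bit and unmapped bit), RNAME, POS and CIGAR
#' (M/I/D/N/S plus =/X/H/P) from SAM text; splices (N) split a read into
#' multiple aligned blocks. Coordinates are converted to 0-based half-open.
#'
#' @param path SAM file path.
#' @return data frame of aligned blocks: read_id, chrom, strand, start, end.
#' @export
read_sam_min <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(f, function(x) {
    flag <- as.integer(x[2L])
    if (bitwAnd(flag, 4L) != 0L || x[3L] == "*") return(NULL)
    b <- cigar_to_blocks(as.integer(x[4L]) - 1L, x[6L])
    data.frame(read_id = x[1L], chrom = x[3L],
               strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
               start = b$start, end = b$end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Union-mode read counting over merged gene interval sets
#'
#' A read is assigned to a gene if any of its aligned blocks overlaps any
#' interval of the gene's set and the strand rule passes: 0 ignores strand,
#' 1 requires read strand == gene strand, 2 requires opposite strands
#' (reverse-stranded libraries). Reads overlapping the interval sets of two
#' or more genes are ambiguous and discarded.
#'
#' @param alignments aligned-block data frame (read_id, chrom, strand,
#'   start, end; 0-based half-open), e.g. from [read_sam_min()].
#' @param annot interval-set data frame from [merge_gene_intervals()]
#'   (typically subset to one `kind`).
#' @param strandedness 0, 1 or 2.
#' @return named integer vector of per-gene counts (every gene in `annot`,
#'   zeros included).
#' @export
count_union_mode <- function(alignments, annot, strandedness = 0L) {
  if (!strandedness %in% c(0L, 1L, 2L))
    stop("parameter error: strandedness must be 0, 1 or 2")
  genes <- sort(unique(annot$gene_id))
  counts <- stats::setNames(integer(length(genes)), genes)
  if (nrow(alignments) == 0L) return(counts)
  agr <- GenomicRanges::GRanges(annot$chrom,
                                IRanges::IRanges(annot$start + 1L, annot$end))
  rgr <- GenomicRanges::GRanges(alignments$chrom,
                                IRanges::IRanges(alignments$start + 1L,
                                                 alignments$end))
  ov <- GenomicRanges::findOverlaps(rgr, agr, ignore.strand = TRUE)
  if (length(ov) == 0L) return(counts)
  ri <- S4Vectors::queryHits(ov); ai <- S4Vectors::subjectHits(ov)
  pass <- switch(as.character(strandedness),
                 "0" = rep(TRUE, length(ri)),
                 "1" = alignments$strand[ri] == annot$strand[ai],
                 "2" = alignments$strand[ri] != annot$strand[ai])
  pairs <- unique(data.frame(read = alignments$read_id[ri][pass],
                             gene = annot$gene_id[ai][pass],
                             stringsAsFactors = FALSE))
  n_genes_per_read <- table(pairs$read)
  unambig <- pairs[pairs$read %in%
                     names(n_genes_per_read)[n_genes_per_read == 1L], ]
  tab <- table(factor(unambig$gene, levels = genes))
  counts[] <- as.integer(tab)
  counts
}

#' Simulate a toy gene annotation and uniformly placed reads
#'
#' Lays `n_genes` genes along one chromosome, each with 1-3 transcripts of
#' 2-5 exons, and places single-block reads uniformly over the chromosome
#' with random strands. Used to validate the interval engine against
#' per-base brute-force oracles.
#'
#' @param n_genes number of genes.
#' @param n_reads number of reads.
#' @param read_len read length (bp).
#' @param seed RNG seed.
#' @return list with `models` (exon table), `alignments` (block table) and
#'   `chrom_len`.
#' @export
simulate_toy_annotation <- function(n_genes = 20L, n_reads = 1000L,
                                    read_len = 50L, seed = 1L) {
  set.seed(seed)
  cursor <- 0L
  rows <- list()
  for (g in seq_len(n_genes)) {
    gene_start <- cursor + sample(100:400, 1L)
    n_ex <- sample(2:5, 1L)
    ex_len <- sample(80:300, n_ex, replace = TRUE)
    gaps <- sample(50:400, n_ex - 1L, replace = TRUE)
    starts <- gene_start + cumsum(c(0L, ex_len[-n_ex] + gaps))
    ends <- starts + ex_len
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("g%03d", g)
    n_tx <- sample(1:3, 1L)
    for (t in seq_len(n_tx)) {
      keep <- sort(unique(c(1L, n_ex, which(stats::runif(n_ex) < 0.8))))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = paste0(gid, ".t", t), chrom = "chr1",
        strand = strand, start = starts[keep], end = ends[keep],
        stringsAsFactors = FALSE)
    }
    cursor <- max(ends)
  }
  models <- do.call(rbind, rows)
  chrom_len <- cursor + 500L
  starts <- sample.int(chrom_len - read_len, n_reads, replace = TRUE) - 1L
  alignments <- data.frame(
    read_id = sprintf("r%05d", seq_len(n_reads)), chrom = "chr1",
    strand = sample(c("+", "-"), n_reads, replace = TRUE),
    start = starts, end = starts + read_len, stringsAsFactors = FALSE)
  list(models = models, alignments = alignments, chrom_len = chrom_len)
}
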