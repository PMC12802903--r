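# Shared fixture builders: all fixtures are generated in code.

# single-family miRNA table for simulations that need one focal family
one_family_table <- function(groups = c("wt", "mut"), fc = 1 / 6) {
  tab <- data.frame(mirna_id = "miR-X-5p", family = "miR-X",
                    sequence = "UAAUACUGCCUGGUAAUGAUGA",
                    is_spike_in = FALSE, baseline = 1000,
                    stringsAsFactors = FALSE)
  for (g in groups[-1]) tab[[paste0("fc_", g)]] <- fc
  tab
}

# two-group config with a single focal miRNA family and no TF program
two_group_config <- function(seed, mir_log2fc, mir_target_fraction = 0.25,
                             n_genes = 2000, n_per_group = 4, ...) {
  sim_config(n_genes = n_genes, n_per_group = n_per_group,
             groups = c("wt", "mut"),
             group_effect_scale = c(wt = 0, mut = 1),
             tf_target_fraction = 0, transcriptome_effect_sd = 0,
             mir_target_fraction = mir_target_fraction,
             mir_log2fc = mir_log2fc,
             mirna_families = one_family_table(), seed = seed, ...)
}

# hand-built DE result for statistic-level tests
toy_de <- function(gene_id, lfc, padj = rep(1, length(gene_id)),
                   raw_mean = rep(100, length(gene_id)),
                   control_cpm = rep(10, length(gene_id))) {
  res <- data.frame(gene_id = gene_id, baseMean = raw_mean,
                    log2FoldChange = lfc, lfcSE = 0.1,
                    stat = lfc / 0.1, pvalue = padj, padj = padj,
                    controlCPM = control_cpm, rawMean = raw_mean,
                    converged = TRUE, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

# independent per-base brute-force counter (oracle for count_union_mode):
# per gene, accumulate which reads have any base overlap with any interval,
# then apply the strand rule and the discard-ambiguous rule.
brute_force_counts <- function(alignments, annot, strandedness) {
  genes <- sort(unique(annot$gene_id))
  reads <- unique(alignments$read_id)
  hit <- matrix(FALSE, nrow = length(reads), ncol = length(genes),
                dimnames = list(reads, genes))
  for (g in genes) {
    iv <- annot[annot$gene_id == g, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      ov <- alignments$chrom == iv$chrom[i] &
        alignments$start < iv$end[i] & alignments$end > iv$start[i]
      strand_ok <- switch(as.character(strandedness),
                          "0" = TRUE,
                          "1" = alignments$strand == iv$strand[i],
                          "2" = alignments$strand != iv$strand[i])
      ids <- alignments$read_id[ov & strand_ok]
      hit[match(unique(ids), reads), g] <- TRUE
    }
  }
  n_per_read <- rowSums(hit)
  counts <- colSums(hit[n_per_read == 1L, , drop = FALSE])
  storage.mode(counts) <- "integer"
  counts
}

# full-enumeration two-sided Mann-Whitney oracle (tie-free inputs)
enumerate_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2L, function(i) {
    sum(rank(pooled)[i]) - nx * (nx + 1) / 2
  })
  p_low <- mean(us <= u_obs)
  p_high <- mean(us >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# step-up BH oracle by direct enumeration
bh_oracle <- function(p) {
  ok <- !is.na(p)
  q <- p[ok]
  m <- length(q)
  o <- order(q)
  adj <- numeric(m)
  cummin_rev <- rev(cummin(rev(m * q[o] / seq_len(m))))
  adj[o] <- pmin(1, cummin_rev)
  out <- rep(NA_real_, length(p))
  out[ok] <- adj
  out
}

# hypergeometric two-sided Fisher oracle: sum of table probabilities <= obs
fisher_oracle_p <- function(q, m, n, k) {
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(q, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
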