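#!/usr/bin/env Rscript
# Step 2: two-group NB Wald differential expression, per contrast and per
# annotation level (exon / merged-intron), plus variable-gene PCA.
# Reads results/sim/, writes DE tables and PCA scores under results/de/.

suppressMessages(library(mirderep))

read_counts <- function(path, meta) {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(m, meta)
}

meta <- read_tsv_plain("results/sim/samples.tsv")
exon <- read_counts("results/sim/exon_counts.tsv", meta)
intron <- read_counts("results/sim/intron_counts.tsv", meta)
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

for (test in c("het", "hom")) {
  for (level in c("exon", "intron")) {
    cm <- if (level == "exon") exon else intron
    de <- run_de(cm, "wt", test)
    write_de_result(de, sprintf("results/de/%s_%s_vs_wt.tsv", level, test))
    flt <- apply_plot_filters(de)
    n_deg <- sum(flt$de$padj < 0.05, na.rm = TRUE)
    n_dn <- sum(flt$de$padj < 0.05 & flt$de$log2FoldChange < 0, na.rm = TRUE)
    message(sprintf(
      "%s %s vs wt: %d genes pass filters, %d DE (padj<0.05), %d%% down",
      level, test, nrow(flt$de), n_deg,
      if (n_deg > 0) round(100 * n_dn / n_deg) else 0))
  }
}

pca <- variable_gene_pca(exon, n_variable = 2000)
scores <- data.frame(sample_id = rownames(pca$scores), pca$scores,
                     check.names = FALSE)
write_tsv_plain(scores, "results/de/pca_scores.tsv")
message(sprintf("PCA: PC1 explains %.1f%% of variance; %d components kept",
                100 * pca$variance_explained[1], ncol(pca$scores)))
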