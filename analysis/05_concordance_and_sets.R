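#!/usr/bin/env Rscript
# Step 5: comparative statistics downstream of differential expression —
# exon/intron fold-change concordance (transcriptional vs
# post-transcriptional inference), overlap of exon- and intron-level DE
# calls, the het/hom fold-change regression, and a gene-set shift test
# between the planted repressed (TF-target) and derepressed (miRNA-target)
# programs. Writes tables under results/concordance/.

suppressMessages(library(mirderep))

read_de <- function(path) {
  de <- read_tsv_plain(path)
  class(de) <- c("de_result", "data.frame")
  de
}
de_ex_hom <- read_de("results/de/exon_hom_vs_wt.tsv")
de_in_hom <- read_de("results/de/intron_hom_vs_wt.tsv")
de_ex_het <- read_de("results/de/exon_het_vs_wt.tsv")
truth <- read_tsv_plain("results/sim/truth.tsv")
dir.create("results/concordance", showWarnings = FALSE, recursive = TRUE)

fe <- apply_plot_filters(de_ex_hom)$de
fi <- apply_plot_filters(de_in_hom)$de
cc <- exon_intron_concordance(fe, fi)
write_tsv_plain(cc$genes, "results/concordance/exon_intron_genes.tsv")
message(sprintf("exon/intron concordance: n=%d, Pearson R^2 = %.2f",
                cc$n, cc$r_squared))
for (d in c("up", "down")) {
  o <- cc$overlap[[d]]
  message(sprintf(
    "  %-4s DE overlap: %d exon, %d intron, %d shared (Fisher p = %.2e)",
    d, o$n_exon, o$n_intron, o$n_both, o$p))
}

tr <- merge(cc$genes, truth[, c("gene_id", "set")], by = "gene_id")
tr <- tr[!is.na(tr$set), ]
acc <- mean(tr$class == ifelse(tr$set == "tf_target", "transcriptional",
                               "post_transcriptional"))
message(sprintf(
  "planted-set classification by concordance quadrant: %.1f%% of %d genes",
  100 * acc, nrow(tr)))

reg <- fc_regression(de_ex_het, de_ex_hom)
write_tsv_plain(data.frame(slope = reg$slope, intercept = reg$intercept,
                           ci_lo = reg$ci[1], ci_hi = reg$ci[2],
                           r_squared = reg$r_squared, n = reg$n),
                "results/concordance/het_hom_regression.tsv")
message(sprintf(
  "het/hom fold-change regression: slope %.3f (95%% CI %.3f-%.3f), R^2 %.2f",
  reg$slope, reg$ci[1], reg$ci[2], reg$r_squared))

# shift between the planted repressed and derepressed programs
setA <- truth$gene_id[truth$set %in% "tf_target"]
setB <- truth$gene_id[truth$set %in% "mir_target"]
setA <- intersect(setA, de_ex_hom$gene_id[is.finite(de_ex_hom$log2FoldChange)])
setB <- intersect(setB, de_ex_hom$gene_id[is.finite(de_ex_hom$log2FoldChange)])
sh <- geneset_shift(de_ex_hom, setA, setB)
message(sprintf(
  "gene-set shift (TF targets vs miRNA targets): means %+.2f vs %+.2f, t = %.1f, p = %.2e",
  sh$mean_A, sh$mean_B, sh$t, sh$p))
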