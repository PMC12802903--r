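#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Emulates the design of a pituitary derepression study: wild-type plus
# heterozygous and homozygous knock-in groups (4 replicates each), a planted
# transcriptionally repressed TF-target program (exons AND introns down), a
# planted post-transcriptionally derepressed miRNA-target program (exons
# only), a widespread downstream transcriptional program, and a 3'-UTR
# length bias on miRNA targets. Writes count matrices, planted truth,
# predictions, UTR table and the config itself under results/sim/.

suppressMessages(library(mirderep))

cfg <- sim_config(
  n_genes = 4000,
  n_per_group = 4,
  groups = c("wt", "het", "hom"),
  group_effect_scale = c(wt = 0, het = 1, hom = 1.1),
  tf_target_fraction = 0.05, tf_log2fc = -1,
  mir_target_fraction = 0.10, mir_log2fc = log2(1.25),
  mir_effect_scaling = "score",
  utr_length_bias = 1,
  seed = 20260101)

sim <- simulate_counts(cfg)
dir <- "results/sim"
write_sim_outputs(sim, cfg, dir)

message(sprintf("simulated %d genes x %d samples (%s)",
                nrow(sim$exon$counts), ncol(sim$exon$counts),
                paste(cfg$groups, collapse = "/")))
message(sprintf("planted: %d TF targets (log2FC %.2f, exon+intron), ",
                sum(sim$truth$set %in% "tf_target"), cfg$tf_log2fc),
        sprintf("%d miRNA targets (median log2FC %.3f, exon only)",
                sum(sim$truth$set %in% "mir_target"), cfg$mir_log2fc))
message("outputs under ", dir)
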