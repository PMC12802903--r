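test_that("null configuration plants no effects and group means agree", {
  cfg <- two_group_config(seed = 11, mir_log2fc = 0, n_genes = 800,
                          n_per_group = 6)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$true_exon_lfc_mut == 0))
  expect_true(all(sim$truth$true_intron_lfc_mut == 0))
  cm <- sim$exon
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  grp <- cm$meta$group
  lr <- log2(rowMeans(norm[, grp == "mut"]) / rowMeans(norm[, grp == "wt"]))
  expect_lt(abs(mean(lr[is.finite(lr)])), 0.05)
})

test_that("counts obey the NB mean-variance relationship", {
  # Poisson limit: dispersion trend (0, 0) gives variance ~ mean
  cfg <- sim_config(n_genes = 2000, n_per_group = 10,
                    groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1),
                    nb_dispersion_params = c(0, 0),
                    library_size_range = c(1e6, 1e6),
                    tf_target_fraction = 0, mir_target_fraction = 0,
                    transcriptome_effect_sd = 0, seed = 21)
  sim <- simulate_counts(cfg)
  k <- sim$exon$counts
  ratio <- apply(k, 1, var) / rowMeans(k)
  expect_gt(median(ratio), 0.9)
  expect_lt(median(ratio), 1.1)

  # configured dispersion recovered by the moment identity var = mu + a*mu^2
  cfg2 <- sim_config(n_genes = 2000, n_per_group = 10,
                     groups = c("wt", "mut"),
                     group_effect_scale = c(wt = 0, mut = 1),
                     nb_dispersion_params = c(0.3, 0),
                     library_size_range = c(1e6, 1e6),
                     tf_target_fraction = 0, mir_target_fraction = 0,
                     transcriptome_effect_sd = 0, seed = 22)
  k2 <- simulate_counts(cfg2)$exon$counts
  mu <- rowMeans(k2)
  a_hat <- (apply(k2, 1, var) - mu) / mu^2
  expect_gt(median(a_hat), 0.24)
  expect_lt(median(a_hat), 0.36)
})

test_that("simulation is deterministic and streams are independent", {
  cfg <- two_group_config(seed = 31, mir_log2fc = 0.5, n_genes = 300)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$exon$counts, b$exon$counts)
  expect_identical(a$intron$counts, b$intron$counts)
  expect_identical(a$truth, b$truth)
  # changing a read-only knob must not perturb the count streams
  cfg2 <- cfg
  cfg2$subq30_read_fraction <- 0.5
  c2 <- simulate_counts(cfg2)
  expect_identical(a$exon$counts, c2$exon$counts)
})

test_that("planted effects are recoverable from group-mean ratios", {
  cfg <- sim_config(n_genes = 600, n_per_group = 16,
                    groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1),
                    library_size_range = c(1e6, 1e6),
                    tf_target_fraction = 0.2, tf_log2fc = -1,
                    mir_target_fraction = 0.2, mir_log2fc = 0.5,
                    transcriptome_effect_sd = 0, seed = 41)
  sim <- simulate_counts(cfg)
  grp <- sim$exon$meta$group
  lr <- function(k) log2(rowMeans(k[, grp == "mut"]) /
                           rowMeans(k[, grp == "wt"]))
  ex <- lr(sim$exon$counts); it <- lr(sim$intron$counts)
  tf <- sim$truth$set %in% "tf_target"
  mir <- sim$truth$set %in% "mir_target"
  expect_lt(abs(mean(ex[tf]) - -1), 0.1)
  expect_lt(abs(mean(it[tf]) - -1), 0.1)
  expect_lt(abs(mean(ex[mir]) - 0.5), 0.1)
  expect_lt(abs(mean(it[mir])), 0.1)  # post-transcriptional: introns flat
})

test_that("small-RNA read simulation matches its multinomial truth", {
  # degenerate distribution: one biological species, no spike-ins
  fam <- one_family_table()
  cfg <- sim_config(mirna_families = fam, spikein_proportion = 0,
                    groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1),
                    subq30_read_fraction = 0, seed = 51)
  sr <- simulate_small_rna_reads(cfg, n_reads = 500)
  expect_true(all(grepl(chartr("U", "T", fam$sequence[1]), sr$reads$sequence,
                        fixed = TRUE)))
  expect_equal(sum(sr$true_counts$count), 500)

  # 50/50 species within 3 binomial SD, spike-ins near their proportion
  fam2 <- rbind(fam,
                data.frame(mirna_id = "miR-Y-5p", family = "miR-Y",
                           sequence = "UGAGGUAGUAGGUUGUAUAGUU",
                           is_spike_in = FALSE, baseline = 1000, fc_mut = 1),
                data.frame(mirna_id = "spike-synth", family = "spike",
                           sequence = "ACGUACGGUUCAGACCAUGGAC",
                           is_spike_in = TRUE, baseline = NA, fc_mut = NA))
  cfg2 <- sim_config(mirna_families = fam2, spikein_proportion = 0.01,
                     groups = c("wt", "mut"),
                     group_effect_scale = c(wt = 0, mut = 1),
                     subq30_read_fraction = 0, seed = 52)
  n <- 2e4
  sr2 <- simulate_small_rna_reads(cfg2, n_reads = n)
  cts <- setNames(sr2$true_counts$count, sr2$true_counts$mirna_id)
  p_each <- 0.99 / 2
  expect_lt(abs(cts[["miR-X-5p"]] - n * p_each),
            3 * sqrt(n * p_each * (1 - p_each)))
  expect_lt(abs(cts[["spike-synth"]] - n * 0.01),
            3 * sqrt(n * 0.01 * 0.99))

  # zero reads: empty FASTQ, zero truth
  sr0 <- simulate_small_rna_reads(cfg2, n_reads = 0)
  expect_equal(nrow(sr0$reads), 0)
  expect_true(all(sr0$true_counts$count == 0))
})

test_that("UTR lengths are length-biased for targets as configured", {
  cfg0 <- two_group_config(seed = 61, mir_log2fc = 0,
                           mir_target_fraction = 0.25, n_genes = 2000,
                           utr_length_bias = 0)
  sim0 <- simulate_counts(cfg0)
  u0 <- simulate_utr_table(cfg0, sim0$truth)
  is_t <- sim0$truth$set %in% "mir_target"
  ks <- suppressWarnings(ks.test(u0$utr_length[is_t], u0$utr_length[!is_t]))
  expect_gt(ks$p.value, 0.01)

  cfg1 <- two_group_config(seed = 61, mir_log2fc = 0,
                           mir_target_fraction = 0.25, n_genes = 2000,
                           utr_length_bias = 1)
  sim1 <- simulate_counts(cfg1)
  u1 <- simulate_utr_table(cfg1, sim1$truth)
  is_t1 <- sim1$truth$set %in% "mir_target"
  ratio <- median(u1$utr_length[is_t1]) / median(u1$utr_length[!is_t1])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  expect_true(all(u1$utr_length >= 1))
  expect_identical(u1, simulate_utr_table(cfg1, simulate_counts(cfg1)$truth))
})

test_that("invalid configurations are rejected and YAML round-trips", {
  expect_error(two_group_config(seed = 1, mir_log2fc = 0,
                                mir_target_fraction = 1.2),
               "fractions")
  expect_error(sim_config(groups = c("wt", "mut"),
                          group_effect_scale = c(wt = 0.5, mut = 1)),
               "control group")
  expect_error(sim_config(library_size_range = c(-1, 10)), "library_size")
  cfg <- two_group_config(seed = 71, mir_log2fc = 0.3)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$mir_log2fc, cfg$mir_log2fc)
  expect_identical(simulate_counts(cfg)$exon$counts,
                   simulate_counts(cfg2)$exon$counts)
})
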