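test_that("UTR binning builds equal-count bins deterministically", {
  u <- data.frame(gene_id = sprintf("g%02d", 1:20), utr_length = 1:20)
  b <- bin_utrs(u, 10)
  expect_equal(as.integer(table(b)), rep(2L, 10))
  expect_equal(unname(b[c("g01", "g02", "g19", "g20")]), c(1L, 1L, 10L, 10L))
  # order invariance
  perm <- u[sample(20), ]
  expect_equal(bin_utrs(perm, 10)[names(b)], b)
  # equal bin sizes whenever n divides evenly
  set.seed(3)
  u2 <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   utr_length = sample(1e5, 200))
  expect_equal(as.integer(table(bin_utrs(u2, 10))), rep(20L, 10))
  expect_error(bin_utrs(u[1:5, ], 10), "fewer genes")
  expect_error(bin_utrs(data.frame(gene_id = c("a", "a"),
                                   utr_length = c(1, 2)), 2), "one length")
})

test_that("matched sampling preserves the bin histogram exactly", {
  u <- data.frame(gene_id = sprintf("g%02d", 1:20), utr_length = 1:20)
  bins <- bin_utrs(u, 5)
  targets <- c("g01", "g02", "g09", "g17")
  pool <- setdiff(names(bins), targets)
  for (s in 1:10) {
    co <- sample_matched_nontargets(targets, pool, bins, seed = s)
    expect_equal(unname(table(factor(bins[co], 1:5))),
                 unname(table(factor(bins[targets], 1:5))))
    expect_true(all(co %in% pool))
  }
  # forced draw when a bin holds a single nontarget
  co1 <- sample_matched_nontargets(c("g01", "g02", "g03"), "g04", bins, 1)
  expect_equal(co1, rep("g04", 3))
  # empty bin is an error that names the bin
  expect_error(sample_matched_nontargets("g20", c("g01", "g02"), bins, 1),
               "bin 5")
  # with-replacement draws are uniform within the bin
  bins2 <- stats::setNames(rep(1L, 3), c("t1", "n1", "n2"))
  draws <- sample_matched_nontargets(rep("t1", 1e4), c("n1", "n2"), bins2, 9)
  expect_lt(abs(mean(draws == "n1") - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("Mann-Whitney matches full enumeration on small tie-free inputs", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)
  expect_equal(r$method, "exact")
  set.seed(13)
  for (i in 1:60) {
    nx <- sample(2:7, 1); ny <- sample(2:7, 1)
    v <- sample(1000, nx + ny)  # tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    ours <- mann_whitney(x, y)
    expect_equal(ours$p, enumerate_mw_p(x, y))
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(wt$statistic))
    expect_equal(ours$p, wt$p.value)
  }
})

test_that("Mann-Whitney handles ties via the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 3, 3, 4, 5, 6)
  ours <- mann_whitney(x, y)
  expect_equal(ours$method, "normal")
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, wt$p.value, tolerance = 1e-10)
  # identical multisets: p = 1 by symmetry
  expect_equal(mann_whitney(c(1, 2, 2, 9), c(1, 2, 2, 9))$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney rejection rate is calibrated under the null", {
  set.seed(23)
  rej <- mean(replicate(400, {
    mann_whitney(rnorm(50), rnorm(50))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("the median-difference statistic carries both orientations", {
  de <- toy_de(c(paste0("t", 1:3), paste0("n", 1:3)),
               lfc = c(0.3, 0.3, 0.3, 0, 0, 0))
  st <- repression_statistic(de, paste0("t", 1:3), paste0("n", 1:3))
  expect_equal(st$derepression, 0.3)
  expect_equal(st$repression, -0.3)
  # identical distributions give zero
  st0 <- repression_statistic(de, paste0("t", 1:3), paste0("t", 1:3))
  expect_equal(st0$derepression, 0)
  # equals direct median subtraction on random sets
  set.seed(33)
  de2 <- toy_de(sprintf("g%03d", 1:100), lfc = rnorm(100))
  tg <- sample(de2$gene_id, 20); co <- sample(de2$gene_id, 20, replace = TRUE)
  st2 <- repression_statistic(de2, tg, co)
  lfc <- setNames(de2$log2FoldChange, de2$gene_id)
  expect_equal(st2$derepression, median(lfc[tg]) - median(lfc[co]))
  expect_error(repression_statistic(de2, c(tg, "missing"), co), "missing")
})

test_that("the replicated target analysis is reproducible and aggregates", {
  cfg <- two_group_config(seed = 43, mir_log2fc = log2(1.25),
                          n_genes = 1200, mir_target_fraction = 0.2)
  sim <- simulate_counts(cfg)
  de <- run_de(sim$exon, "wt", "mut")
  utrs <- simulate_utr_table(cfg, sim$truth)
  r1 <- run_target_analysis(de, sim$predictions, utrs, "miR-X",
                            n_replicates = 1, seed = 5)
  expect_equal(r1$summary$mean_derepression[r1$summary$set == "all"],
               r1$replicates$derepression[r1$replicates$set == "all"])
  r21a <- run_target_analysis(de, sim$predictions, utrs, "miR-X", seed = 5)
  r21b <- run_target_analysis(de, sim$predictions, utrs, "miR-X", seed = 5)
  expect_identical(r21a$summary, r21b$summary)
  expect_identical(r21a$ecdf, r21b$ecdf)
  expect_error(run_target_analysis(de, sim$predictions, utrs, "miR-X",
                                   n_replicates = 20), "odd")
  # the ECDF output contains the three target sets plus the matched cohort
  expect_setequal(unique(r21a$ecdf$set),
                  c("all", "conserved", "top", "matched_nontarget"))
  # an unknown family yields flagged empty rows, not an error
  r0 <- run_target_analysis(de, sim$predictions, utrs, "miR-nope", seed = 5)
  expect_true(all(r0$summary$empty))
})

test_that("excluded families are removed from target sets and pool", {
  de <- toy_de(sprintf("g%02d", 1:40), lfc = rnorm(40, sd = 0.1))
  utrs <- data.frame(gene_id = de$gene_id, utr_length = seq(100, 4000, 100))
  preds <- data.frame(
    gene_id = c("g01", "g02", "g03", "g02", "g10"),
    family = c("famA", "famA", "famA", "famB", "famB"),
    context_score = c(-0.5, -0.4, -0.3, -0.2, -0.6),
    conserved = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  rep <- run_target_analysis(de, preds, utrs, "famA",
                             exclude_families = "famB",
                             min_raw_mean = 0, n_bins = 4,
                             n_replicates = 3, seed = 1)
  # g02 is also a famB target, so the famA 'all' set is g01 and g03
  expect_equal(rep$summary$n_targets[rep$summary$set == "all"], 2L)
  # pool excludes famA targets (g01-g03) and famB targets (g02, g10)
  expect_equal(rep$n_pool, 36L)
})

test_that("higher-confidence target sets show stronger planted derepression", {
  dd <- sapply(1:3, function(i) {
    cfg <- two_group_config(seed = 400 + i, mir_log2fc = log2(1.25),
                            mir_target_fraction = 0.25,
                            mir_effect_scaling = "score")
    sim <- simulate_counts(cfg)
    de <- run_de(sim$exon, "wt", "mut")
    rep <- run_target_analysis(de, sim$predictions,
                               simulate_utr_table(cfg, sim$truth),
                               "miR-X", n_replicates = 5, seed = cfg$seed)
    s <- rep$summary
    c(all = s$mean_derepression[s$set == "all"],
      cons = s$mean_derepression[s$set == "conserved"],
      top = s$mean_derepression[s$set == "top"])
  })
  m <- rowMeans(dd)
  expect_gt(m["top"], m["cons"])
  expect_gt(m["cons"], m["all"])
})

test_that("family selection applies inclusive thresholds", {
  preds <- data.frame(
    gene_id = sprintf("g%03d", 1:300),
    family = rep(c("famA", "famB", "famC"), each = 100),
    context_score = -runif(300),
    conserved = TRUE)
  stats <- data.frame(
    family = c("famA", "famB", "famC", "famD"),
    control_cpm = c(999, 1000, 5000, 5000),
    padj = c(0.001, 0.001, 0.2, 0.001))
  out <- select_families(stats, preds, min_conserved = 100)
  # famA fails CPM (999 < 1000); famB passes at both boundaries exactly;
  # famC not DE; famD has no conserved targets
  expect_equal(out$family, "famB")
  expect_equal(out$n_conserved, 100L)
  # exclusion shrinks the conserved count below threshold
  out2 <- select_families(stats, preds, exclude_families = "famB",
                          min_conserved = 100)
  expect_false("famB" %in% out2$family)
})
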