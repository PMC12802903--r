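mk_reads <- function(seqs, quals = NULL) {
  data.frame(read_id = sprintf("r%03d", seq_along(seqs)), sequence = seqs,
             quality = quals %||% strrep("F", nchar(seqs)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
q_chr <- function(q) rawToChar(as.raw(q + 33L))

test_that("the Q30 filter is inclusive and tallies drops", {
  r <- mk_reads(c("ACGTACGT", "ACGTACGT", "ACGTACGT"),
                c(strrep(q_chr(30), 8),                       # all exactly Q30
                  paste0(strrep(q_chr(40), 7), q_chr(29)),     # one Q29 base
                  strrep(q_chr(37), 8)))
  out <- quality_filter(r, min_q = 30, min_frac = 1)
  expect_equal(out$read_id, c("r001", "r003"))
  expect_equal(attr(out, "n_filtered"), 1L)
  # fractional threshold
  out2 <- quality_filter(r, min_q = 30, min_frac = 0.8)
  expect_equal(nrow(out2), 3)
  # malformed record: quality shorter than sequence
  bad <- mk_reads("ACGT", "FF")
  expect_error(quality_filter(bad), "index 1")
})

test_that("quality-filter retention matches the generated sub-Q30 fraction", {
  cfg <- sim_config(groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1),
                    mirna_families = one_family_table(),
                    subq30_read_fraction = 0.1, seed = 81)
  sr <- simulate_small_rna_reads(cfg, n_reads = 1e4)
  kept <- nrow(quality_filter(sr$reads))
  expect_lt(abs(kept / 1e4 - 0.9), 3 * sqrt(0.9 * 0.1 / 1e4))
})

test_that("adapter trimming recovers the planted mature sequence exactly", {
  mir <- "TAACACTGTCTGGTAACGATGT"  # 22 nt
  read <- paste0("GGGG", mir, "TTTT", default_adapter3())
  out <- trim_adapters(mk_reads(read))
  expect_equal(out$sequence, mir)
  # no adapter: dropped and tallied
  out2 <- trim_adapters(mk_reads(c(read, strrep("A", 50))))
  expect_equal(nrow(out2), 1)
  expect_equal(attr(out2, "n_no_adapter"), 1L)
  # post-trim too short: dropped
  short <- paste0("GGGG", "ACGTACGTAC", "TTTT", default_adapter3())
  out3 <- trim_adapters(mk_reads(short))
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_too_short"), 1L)
  expect_error(trim_adapters(mk_reads(read), "ACGT"), ">= 8")
})

test_that("generator reads all recover their planted mature sequences", {
  cfg <- sim_config(groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1),
                    subq30_read_fraction = 0, seed = 91)
  sr <- simulate_small_rna_reads(cfg, n_reads = 2000)
  tr <- trim_adapters(sr$reads)
  expect_equal(nrow(tr), 2000)
  expected <- rep(chartr("U", "T", cfg$mirna_families$sequence),
                  sr$true_counts$count[match(cfg$mirna_families$mirna_id,
                                             sr$true_counts$mirna_id)])
  tab <- function(x) {
    t <- table(x)
    setNames(as.integer(t), names(t))
  }
  a <- tab(tr$sequence); b <- tab(expected)
  expect_equal(a[order(names(a))], b[order(names(b))])
})

test_that("dictionary validation enforces the prefix-collision policy", {
  # same 19-nt prefix, different full sequence: hard error
  d <- data.frame(mirna_id = c("a", "b"),
                  sequence = c("ACGTACGTACGTACGTACGTAA",
                               "ACGTACGTACGTACGTACGTGG"))
  expect_error(load_mirna_dictionary(d, k = 19), "ambiguous")
  expect_s3_class(load_mirna_dictionary(d, k = 21), "mirna_dictionary")
  # identical mature sequences: error unless collapse is requested
  d2 <- data.frame(mirna_id = c("a", "b"),
                   sequence = rep("ACGUACGUACGUACGUACGUAA", 2))
  expect_error(load_mirna_dictionary(d2, k = 19), "identical")
  merged <- load_mirna_dictionary(d2, k = 19, collapse_identical = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$mirna_id, "a;b")
  # U -> T normalization and length check
  expect_equal(merged$sequence, "ACGTACGTACGTACGTACGTAA")
  expect_error(load_mirna_dictionary(
    data.frame(mirna_id = "x", sequence = "ACGT"), k = 19), ">= prefix")
})

test_that("exact-prefix matching counts, removes spikes, and conserves reads", {
  d <- load_mirna_dictionary(data.frame(
    mirna_id = c("mirA", "mirB", "spike1"),
    sequence = c("TAACACTGTCTGGTAACGATGT", "TGAGGTAGTAGGTTGTATAGTT",
                 "ACGTACGGTTCAGACCATGGAC"),
    is_spike_in = c(FALSE, FALSE, TRUE)), k = 19)
  reads <- c("TAACACTGTCTGGTAACGATGT",       # identical to mirA
             "TAACACTGTCTGGTAACGA",           # exactly k nt, still mirA
             "TACCACTGTCTGGTAACGATGT",        # differs at position 3
             "ACGTACGGTTCAGACCATGGAC",        # spike-in
             "TGAGGTAGTAGGTTGTATAGTTXX")      # mirB with trailing junk
  mc <- match_prefix(reads, d)
  expect_equal(unname(mc$counts[c("mirA", "mirB")]), c(2L, 1L))
  expect_equal(mc$totals$removed_spike, 1L)
  expect_equal(mc$totals$unmatched, 1L)
  expect_equal(with(mc$totals, matched + unmatched + removed_spike), 5L)
  # order invariance
  mc2 <- match_prefix(rev(reads), d)
  expect_identical(mc$counts, mc2$counts)
})

test_that("CPM normalization is a per-sample proportion times 1e6", {
  m <- matrix(c(2, 8), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(as.numeric(mirna_cpm(m)), c(2e5, 8e5))
  set.seed(4)
  m2 <- matrix(rpois(30, 50), nrow = 5,
               dimnames = list(letters[1:5], paste0("s", 1:6)))
  sfx <- runif(6, 0.5, 2)
  cpm <- mirna_cpm(m2, sfx)
  expect_equal(unname(colSums(cpm)), rep(1e6, 6))
  # equal factors reduce to raw proportions
  expect_equal(mirna_cpm(m2, rep(2, 6)), mirna_cpm(m2))
  expect_error(mirna_cpm(matrix(0, 2, 1)), "zero-total")
  expect_error(mirna_cpm(m2, c(1, -1, 1, 1, 1, 1)), "> 0")
})

test_that("the full quantification pipeline conserves every read", {
  cfg <- sim_config(groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1), seed = 101)
  sr <- simulate_small_rna_reads(cfg, n_reads = 2e4)
  fam <- cfg$mirna_families
  dict <- load_mirna_dictionary(
    data.frame(mirna_id = fam$mirna_id, family = fam$family,
               sequence = fam$sequence, is_spike_in = fam$is_spike_in),
    k = 19)
  mc <- quantify_mirnas(sr$reads, dict)
  tt <- mc$totals
  expect_equal(tt$matched + tt$unmatched + tt$removed_spike + tt$q_filtered,
               tt$reads_in)
  expect_equal(tt$reads_in, 2e4)
  expect_equal(sum(mc$counts), tt$matched)
  # family-level proportions track planted abundances (Q-filtered reads are
  # missing at random, so proportions are preserved)
  fam_counts <- tapply(mc$counts, dict$family[match(names(mc$counts),
                                                    dict$mirna_id)], sum)
  bio <- fam[!fam$is_spike_in, ]
  planted <- tapply(bio$baseline, bio$family, sum)
  planted <- planted / sum(planted)
  obs <- fam_counts[names(planted)] / sum(fam_counts)
  expect_true(all(abs(obs - planted) <
                    3 * sqrt(planted * (1 - planted) / tt$matched) + 0.005))
})

test_that("FASTQ writing and reading round-trips reads and qualities", {
  cfg <- sim_config(groups = c("wt", "mut"),
                    group_effect_scale = c(wt = 0, mut = 1), seed = 111)
  sr <- simulate_small_rna_reads(cfg, n_reads = 50)
  path <- tempfile(fileext = ".fastq")
  write_fastq(sr$reads, path)
  back <- read_fastq(path)
  expect_equal(back$sequence, sr$reads$sequence)
  expect_equal(back$quality, sr$reads$quality)
  expect_equal(back$read_id, sr$reads$read_id)
})
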