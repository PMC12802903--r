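## The core statistic: de/repression of predicted miRNA target sets against
## 3'-UTR-length-matched nontarget cohorts, by repeated 1:1 resampling.

#' Assign genes to equal-count 3' UTR length bins
#'
#' Quantile (equal-count) bins over the supplied analysis universe. Genes
#' are ordered by length with ties broken by gene id (stable under input
#' permutation) and split into `n_bins` consecutive, as-equal-as-possible
#' groups.
#'
#' @param utrs data frame with columns gene_id, utr_length.
#' @param n_bins number of bins (default 10).
#' @return named integer vector: gene_id -> bin index in 1..n_bins.
#' @export
bin_utrs <- function(utrs, n_bins = 10L) {
  stopifnot(all(c("gene_id", "utr_length") %in% names(utrs)))
  if (any(utrs$utr_length <= 0)) stop("UTR lengths must be positive")
  if (anyDuplicated(utrs$gene_id)) stop("one length per gene required")
  n <- nrow(utrs)
  if (n < n_bins) stop("fewer genes (", n, ") than bins (", n_bins, ")")
  ord <- order(utrs$utr_length, utrs$gene_id)
  bin <- integer(n)
  bin[ord] <- as.integer(floor((seq_len(n) - 1L) * n_bins / n)) + 1L
  stats::setNames(bin, utrs$gene_id)
}

#' Draw a 3'-UTR-length-matched nontarget cohort
#'
#' For each target gene, one nontarget is drawn uniformly with replacement
#' from the nontarget pool of the target's UTR-length bin, so the cohort is
#' a multiset of the same size as the target set with an identical bin
#' histogram. The same nontarget may serve several targets.
#'
#' @param targets character vector of target gene ids.
#' @param pool character vector of eligible nontarget gene ids.
#' @param bins gene -> bin assignment from [bin_utrs()] (must cover targets
#'   and pool).
#' @param seed RNG seed for the draw.
#' @return character vector (multiset) of sampled nontargets, length equal
#'   to `length(targets)`.
#' @export
sample_matched_nontargets <- function(targets, pool, bins, seed = NULL) {
  stopifnot(all(targets %in% names(bins)), all(pool %in% names(bins)))
  if (!is.null(seed)) set.seed(seed)
  tb <- bins[targets]
  pb <- bins[pool]
  out <- character(length(targets))
  for (b in sort(unique(tb))) {
    cand <- pool[pb == b]
    if (length(cand) == 0L)
      stop("UTR bin ", b, " contains targets but no eligible nontargets")
    ti <- which(tb == b)
    out[ti] <- cand[sample.int(length(cand), length(ti), replace = TRUE)]
  }
  out
}

#' Mann-Whitney U test with midrank ties and an exact small-sample path
#'
#' U is computed from midranks. When the samples are tie-free and
#' `n_x * n_y <= 400`, the p-value is exact (null permutation distribution
#' of U); otherwise a normal approximation with tie correction and
#' continuity correction is used. Two-sided by default.
#'
#' @param x,y numeric samples (each nonempty).
#' @param alternative "two.sided" (default), "less" or "greater"
#'   (alternatives refer to the location of `x` relative to `y`).
#' @return list with `U` (statistic for `x`), `p`, and `method`
#'   ("exact" or "normal").
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (!has_ties && nx * ny <= 400) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pwilcox(U, nx, ny),
                                 1 - stats::pwilcox(U - 1, nx, ny))),
      less = stats::pwilcox(U, nx, ny),
      greater = 1 - stats::pwilcox(U - 1, nx, ny))
    return(list(U = U, p = p, method = "exact"))
  }
  N <- nx + ny
  mu <- nx * ny / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(nx * ny / 12 * (N + 1 - tie_term))
  if (sigma == 0) return(list(U = U, p = 1, method = "normal"))
  z <- switch(alternative,
              two.sided = (U - mu - sign(U - mu) * 0.5) / sigma,
              less = (U - mu + 0.5) / sigma,
              greater = (U - mu - 0.5) / sigma)
  p <- switch(alternative,
              two.sided = min(1, 2 * stats::pnorm(-abs(z))),
              less = stats::pnorm(z),
              greater = 1 - stats::pnorm(z))
  list(U = U, p = p, method = "normal")
}

#' Median-difference de/repression statistic for one matched cohort
#'
#' Carries both orientations explicitly: `repression` is the matched
#' nontarget median log2 fold change minus the target median (positive when
#' targets are repressed), and `derepression` is its negation (target minus
#' nontarget; positive when targets rise, the orientation used when a
#' repressing miRNA has been lost). Significance is a Mann-Whitney test
#' between the two log2-fold-change samples.
#'
#' @param de a `de_result` containing all genes involved.
#' @param targets target gene ids.
#' @param cohort matched nontarget gene ids (multiset), e.g. from
#'   [sample_matched_nontargets()].
#' @param alternative passed to [mann_whitney()].
#' @return list: repression, derepression, p, median_target,
#'   median_nontarget.
#' @export
repression_statistic <- function(de, targets, cohort,
                                 alternative = "two.sided") {
  lfc <- stats::setNames(de$log2FoldChange, de$gene_id)
  missing <- setdiff(unique(c(targets, cohort)), de$gene_id)
  if (length(missing))
    stop("genes missing from DE result: ", paste(utils::head(missing, 3L),
                                                 collapse = ", "))
  lt <- lfc[targets]; ln <- lfc[cohort]
  if (anyNA(lt) || anyNA(ln)) stop("all genes must have non-NA log2FC")
  mt <- stats::median(lt); mn <- stats::median(ln)
  mw <- mann_whitney(lt, ln, alternative = alternative)
  list(repression = mn - mt, derepression = mt - mn, p = mw$p,
       median_target = mt, median_nontarget = mn)
}

#' Target-set de/repression analysis with length-matched resampling
#'
#' Builds three target sets for the focal miRNA family -- all predicted
#' targets, the conserved subset, and the top fraction by most-negative
#' cumulative context score -- restricted to the analysis universe (genes in
#' the DE result with non-NA log2 fold change, raw mean count at least
#' `min_raw_mean`, and a known UTR length). The nontarget pool is the
#' universe minus all predicted targets of the focal family and of any
#' excluded families (targets of excluded families are also removed from
#' the target sets). For each set, `n_replicates` length-matched cohorts are
#' drawn and the median-difference statistic and Mann-Whitney p computed;
#' the mean difference in median log2 fold changes and the median p across
#' replicates are reported, together with ECDF curves for each target set
#' and for the all-set's matched cohort from the median-p replicate.
#'
#' @param de a `de_result`.
#' @param predictions data frame: gene_id, family, context_score, conserved.
#' @param utrs data frame: gene_id, utr_length.
#' @param family focal miRNA family.
#' @param exclude_families families whose targets are removed from both the
#'   target sets and the nontarget pool (e.g. the dominant perturbed family
#'   when scoring others).
#' @param top_frac fraction defining the top set (default 0.10).
#' @param min_raw_mean expression filter (default 50 raw counts on average).
#' @param n_bins UTR length bins (default 10).
#' @param n_replicates resampling replicates (odd, default 21).
#' @param seed master seed; replicate r uses a derived per-replicate seed,
#'   reproducible in isolation.
#' @param alternative Mann-Whitney sidedness (default two-sided).
#' @return object of class `repression_report`: `summary` data frame (one
#'   row per set kind: n_targets, mean_derepression, mean_repression,
#'   median_p), `replicates` (per-set per-replicate derepression and p),
#'   `ecdf` (value, cumulative fraction, set label), plus the universe and
#'   pool sizes. Empty sets are flagged in the summary, not raised.
#' @export
run_target_analysis <- function(de, predictions, utrs, family,
                                exclude_families = character(0),
                                top_frac = 0.10, min_raw_mean = 50,
                                n_bins = 10L, n_replicates = 21L,
                                seed = 1L, alternative = "two.sided") {
  stopifnot(top_frac > 0, top_frac <= 1)
  if (n_replicates %% 2L == 0L)
    stop("n_replicates must be odd so the median p is well-defined")
  universe <- de$gene_id[!is.na(de$log2FoldChange) &
                           is.finite(de$log2FoldChange) &
                           de$rawMean >= min_raw_mean]
  universe <- intersect(universe, utrs$gene_id)
  bins <- bin_utrs(utrs[utrs$gene_id %in% universe, , drop = FALSE], n_bins)

  fam_pred <- predictions[predictions$family == family, , drop = FALSE]
  excl_genes <- unique(
    predictions$gene_id[predictions$family %in% exclude_families])
  fam_pred <- fam_pred[!fam_pred$gene_id %in% excl_genes, , drop = FALSE]
  fam_pred <- fam_pred[fam_pred$gene_id %in% universe, , drop = FALSE]

  pool <- setdiff(universe,
                  union(predictions$gene_id[predictions$family == family],
                        excl_genes))

  sets <- list(
    all = fam_pred$gene_id,
    conserved = fam_pred$gene_id[fam_pred$conserved %in% TRUE],
    top = {
      n_top <- max(1L, ceiling(top_frac * nrow(fam_pred)))
      fam_pred$gene_id[order(fam_pred$context_score,
                             fam_pred$gene_id)][seq_len(min(n_top,
                                                            nrow(fam_pred)))]
    })

  rep_rows <- list(); sum_rows <- list(); ecdf_rows <- list()
  lfc <- stats::setNames(de$log2FoldChange, de$gene_id)
  for (kind in names(sets)) {
    tg <- sets[[kind]]
    if (length(tg) == 0L) {
      sum_rows[[kind]] <- data.frame(family = family, set = kind,
                                     n_targets = 0L, mean_derepression = NA,
                                     mean_repression = NA, median_p = NA,
                                     empty = TRUE)
      next
    }
    dd <- numeric(n_replicates); pp <- numeric(n_replicates)
    cohorts <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      co <- sample_matched_nontargets(
        tg, pool, bins, seed = stream_seed(seed, paste0("rep", r)))
      st <- repression_statistic(de, tg, co, alternative = alternative)
      dd[r] <- st$derepression; pp[r] <- st$p
      cohorts[[r]] <- co
    }
    sum_rows[[kind]] <- data.frame(
      family = family, set = kind, n_targets = length(tg),
      mean_derepression = mean(dd), mean_repression = mean(-dd),
      median_p = stats::median(pp), empty = FALSE)
    rep_rows[[kind]] <- data.frame(family = family, set = kind,
                                   replicate = seq_len(n_replicates),
                                   derepression = dd, p = pp)
    v <- sort(lfc[tg])
    ecdf_rows[[kind]] <- data.frame(set = kind, value = as.numeric(v),
                                    cum_frac = seq_along(v) / length(v))
    if (kind == "all") {
      med_rep <- order(pp)[ceiling(n_replicates / 2)]
      v <- sort(lfc[cohorts[[med_rep]]])
      ecdf_rows[["nontarget"]] <- data.frame(
        set = "matched_nontarget", value = as.numeric(v),
        cum_frac = seq_along(v) / length(v))
    }
  }
  out <- list(summary = do.call(rbind, unname(sum_rows)),
              replicates = do.call(rbind, unname(rep_rows)),
              ecdf = do.call(rbind, unname(ecdf_rows)),
              family = family, n_universe = length(universe),
              n_pool = length(pool), n_replicates = n_replicates,
              seed = seed)
  rownames(out$summary) <- NULL
  class(out) <- "repression_report"
  out
}

#' @export
print.repression_report <- function(x, ...) {
  cat(sprintf("repression_report for %s (universe %d, pool %d, %d reps)\n",
              x$family, x$n_universe, x$n_pool, x$n_replicates))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Select miRNA families worth scoring for target de/repression
#'
#' A family qualifies when it is differentially expressed (adjusted p below
#' `alpha`), abundant in the control samples (CPM at least `min_cpm`), and
#' has at least `min_conserved` conserved predicted targets after removal of
#' excluded-family targets. All thresholds are inclusive ("at least").
#'
#' @param family_stats data frame with one row per family: family,
#'   control_cpm, padj.
#' @param predictions prediction table (gene_id, family, conserved).
#' @param exclude_families families whose targets are removed before
#'   counting conserved targets.
#' @param min_cpm abundance threshold (default 1000).
#' @param min_conserved conserved-target threshold (default 100).
#' @param alpha DE threshold on padj (default 0.05, strict <).
#' @return the qualifying subset of `family_stats` with an added
#'   n_conserved column.
#' @export
select_families <- function(family_stats, predictions,
                            exclude_families = character(0),
                            min_cpm = 1000, min_conserved = 100,
                            alpha = 0.05) {
  stopifnot(all(c("family", "control_cpm", "padj") %in% names(family_stats)))
  excl <- unique(predictions$gene_id[predictions$family %in% exclude_families])
  cons <- predictions[predictions$conserved %in% TRUE &
                        !predictions$gene_id %in% excl, , drop = FALSE]
  n_cons <- table(cons$family)
  fs <- family_stats
  fs$n_conserved <- as.integer(n_cons[fs$family])
  fs$n_conserved[is.na(fs$n_conserved)] <- 0L
  keep <- !is.na(fs$padj) & fs$padj < alpha &
    fs$control_cpm >= min_cpm & fs$n_conserved >= min_conserved
  out <- fs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
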