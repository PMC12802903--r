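## Lightweight two-group negative-binomial differential expression:
## median-of-ratios size factors, moment dispersion blended with a
## mean-dependent trend, per-gene NB GLM Wald test (vectorized IRLS), BH.
## This is deliberately a simplified engine, not a re-implementation of
## DESeq2: no empirical-Bayes dispersion shrinkage beyond the 50/50 trend
## blend, no Cook's outlier handling, no independent filtering, no
## fold-change shrinkage.

#' Median-of-ratios size factors
#'
#' For each gene with nonzero counts in all samples, compute the per-sample
#' ratio of its count to its geometric mean across samples; a sample's size
#' factor is the median of those ratios.
#'
#' @param counts integer gene x sample matrix, or a [count_matrix].
#' @return positive per-sample factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; prefilter the matrix ",
         "or check the library depths")
  lg <- log(counts[ok, , drop = FALSE])
  ratio <- exp(lg - rowMeans(lg))
  apply(ratio, 2L, stats::median)
}

#' Gene-wise NB dispersion: method of moments with 50/50 trend shrinkage
#'
#' Normalized counts are pooled within groups to form a pooled within-group
#' variance; the moment estimate `(var - mu) / mu^2` (floored at 1e-8) is
#' then blended 50/50 with a fitted mean-dependent trend
#' `alpha(mu) = a0 + a1 / mu` (ordinary least squares on the raw moment
#' estimates). The blend stabilizes the noisy per-gene moment estimates at
#' small replicate numbers; it is a simpler device than full empirical-Bayes
#' shrinkage and is documented as such.
#'
#' @param counts gene x sample matrix or [count_matrix].
#' @param sf size factors from [size_factors()].
#' @param groups per-sample group labels (taken from the [count_matrix]
#'   metadata when omitted).
#' @return per-gene dispersion vector, with the fitted trend coefficients in
#'   attribute `trend`.
#' @export
estimate_dispersion <- function(counts, sf, groups = NULL) {
  if (inherits(counts, "count_matrix")) {
    groups <- groups %||% counts$meta$group
    counts <- counts$counts
  }
  stopifnot(!is.null(groups), length(groups) == ncol(counts))
  reps <- table(groups)
  if (all(reps < 2L))
    stop("dispersion estimation needs >= 2 replicates in some group")
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  ss <- 0; df <- 0
  for (g in names(reps)[reps >= 2L]) {
    sel <- groups == g
    m <- rowMeans(norm[, sel, drop = FALSE])
    ss <- ss + rowSums((norm[, sel, drop = FALSE] - m)^2)
    df <- df + sum(sel) - 1L
  }
  v <- ss / df
  raw <- (v - mu) / pmax(mu, 1e-8)^2
  use <- mu > 0 & is.finite(raw)
  fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
  a <- pmax(stats::coef(fit), 0)
  trend <- pmax(a[1L] + a[2L] / pmax(mu, 1e-8), 1e-8)
  disp <- pmax(0.5 * pmax(raw, 1e-8) + 0.5 * trend, 1e-8)
  attr(disp, "trend") <- stats::setNames(as.numeric(a), c("a0", "a1"))
  disp
}

#' Two-group negative-binomial Wald test
#'
#' Fits, per gene, an NB GLM with log link, a group indicator and
#' log-size-factor offsets by iteratively reweighted least squares (all
#' genes iterated simultaneously); the reported log2 fold change is the
#' group coefficient divided by ln 2, its standard error comes from the
#' expected information at convergence, and a two-sided normal p-value is
#' attached (no fold-change shrinkage). Genes with zero counts throughout
#' one group get signed infinite log2 fold changes with NA statistics (they
#' are excluded later by the |log2FC| <= 5 plot mask); genes with zero
#' counts everywhere, or that fail to converge, get all-NA statistics.
#'
#' @param counts gene x sample matrix or [count_matrix].
#' @param sf size factors.
#' @param dispersions per-gene dispersions.
#' @param control,test group labels to contrast (test vs control).
#' @param groups per-sample labels (from [count_matrix] metadata if omitted).
#' @param max_iter,tol IRLS controls (relative coefficient change).
#' @return a `de_result` data frame: gene_id, baseMean, log2FoldChange,
#'   lfcSE, stat, pvalue, padj, controlCPM, rawMean, converged.
#' @export
nb_wald <- function(counts, sf, dispersions, control, test, groups = NULL,
                    max_iter = 100L, tol = 1e-8) {
  if (inherits(counts, "count_matrix")) {
    groups <- groups %||% counts$meta$group
    counts <- counts$counts
  }
  stopifnot(!is.null(groups), length(groups) == ncol(counts))
  if (!all(c(control, test) %in% groups))
    stop("both contrast groups must be present in the sample metadata")
  sel <- groups %in% c(control, test)
  y <- counts[, sel, drop = FALSE]
  sfs <- sf[sel]
  x <- as.numeric(groups[sel] == test)
  G <- nrow(y)
  alpha <- rep_len(dispersions, G)

  norm <- sweep(y, 2L, sfs, "/")
  baseMean <- rowMeans(norm)
  cpm <- sweep(norm, 2L, colSums(norm), "/") * 1e6
  controlCPM <- rowMeans(cpm[, x == 0, drop = FALSE])
  rawMean <- rowMeans(y)

  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  fit_ok <- m0 > 0 & m1 > 0

  b0 <- log(pmax(m0, 1e-8))
  b1 <- log(pmax(m1, 1e-8)) - b0
  conv <- !fit_ok  # degenerate genes are not iterated
  active <- which(fit_ok)
  o <- log(sfs)
  se_b1 <- rep(NA_real_, G)
  for (iter in seq_len(max_iter)) {
    if (length(active) == 0L) break
    eta <- b0[active] + outer(b1[active], x) +
      matrix(o, length(active), length(o), byrow = TRUE)
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha[active] * mu)
    z <- (eta - matrix(o, nrow(mu), length(o), byrow = TRUE)) +
      (y[active, , drop = FALSE] - mu) / mu
    A <- rowSums(w)
    B <- rowSums(w[, x == 1, drop = FALSE])
    wz <- w * z
    u <- rowSums(wz)
    v <- rowSums(wz[, x == 1, drop = FALSE])
    denom <- pmax(A - B, 1e-12)
    b0n <- (u - v) / denom
    b1n <- v / pmax(B, 1e-12) - b0n
    step <- pmax(abs(b0n - b0[active]), abs(b1n - b1[active])) /
      pmax(1, abs(b0[active]), abs(b1[active]))
    b0[active] <- b0n
    b1[active] <- b1n
    done <- step < tol
    if (any(done)) {
      idx <- active[done]
      conv[idx] <- TRUE
      # final expected-information SE for the finished genes
      eta <- b0[idx] + outer(b1[idx], x) +
        matrix(o, length(idx), length(o), byrow = TRUE)
      mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
      w <- mu / (1 + alpha[idx] * mu)
      Bf <- rowSums(w[, x == 1, drop = FALSE])
      Af <- rowSums(w)
      se_b1[idx] <- sqrt(1 / pmax(Bf, 1e-12) + 1 / pmax(Af - Bf, 1e-12))
      active <- active[!done]
    }
  }

  log2FC <- b1 / log(2)
  lfcSE <- se_b1 / log(2)
  stat <- log2FC / lfcSE
  pvalue <- 2 * stats::pnorm(-abs(stat))
  # degenerate genes: signed sentinels / NA
  zero_test <- m1 == 0 & m0 > 0
  zero_ctrl <- m0 == 0 & m1 > 0
  zero_both <- m0 == 0 & m1 == 0
  log2FC[zero_test] <- -Inf
  log2FC[zero_ctrl] <- Inf
  log2FC[zero_both] <- NA_real_
  not_est <- zero_test | zero_ctrl | zero_both | (fit_ok & !conv)
  lfcSE[not_est] <- NA_real_
  stat[not_est] <- NA_real_
  pvalue[not_est] <- NA_real_

  res <- data.frame(
    gene_id = rownames(y) %||% sprintf("gene%05d", seq_len(G)),
    baseMean = baseMean, log2FoldChange = log2FC, lfcSE = lfcSE,
    stat = stat, pvalue = pvalue,
    padj = bh_adjust(pvalue),
    controlCPM = controlCPM, rawMean = rawMean,
    converged = conv & !not_est,
    stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper over `stats::p.adjust(method = "BH")`: NAs are
#' propagated and excluded from the number of tests, outputs are monotone
#' and capped at 1.
#'
#' @param p p-values in [0, 1]; NA allowed.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Convenience two-group DE pipeline
#'
#' Size factors, dispersion, Wald test in one call.
#' @param cm a [count_matrix].
#' @param control,test group labels to contrast.
#' @return a `de_result` (see [nb_wald()]).
#' @export
run_de <- function(cm, control, test) {
  sel <- cm$meta$group %in% c(control, test)
  sub <- count_matrix(cm$counts[, sel, drop = FALSE],
                      cm$meta[sel, , drop = FALSE])
  sf <- size_factors(sub)
  disp <- estimate_dispersion(sub, sf)
  nb_wald(sub, sf, disp, control, test)
}

#' Apply the standard plotting/analysis filters to a DE result
#'
#' Three independent, composable masks: control-sample mean CPM above
#' `cpm_min`; |log2 fold change| at most `lfc_bound` (bounds inclusive, so a
#' gene at exactly the bound is retained; infinite sentinels are excluded);
#' and raw mean count at least `min_raw_mean`. Genes with NA fold changes
#' fail the fold-change mask.
#'
#' @param de a `de_result`.
#' @param cpm_min control-CPM threshold (strict >; default 1).
#' @param lfc_bound inclusive |log2FC| bound (default 5).
#' @param min_raw_mean inclusive raw-mean-count threshold (default 50).
#' @return list with `de` (the surviving rows), `keep` (logical mask on the
#'   input) and `tallies` (per-mask exclusion counts).
#' @export
apply_plot_filters <- function(de, cpm_min = 1, lfc_bound = 5,
                               min_raw_mean = 50) {
  stopifnot(all(c(cpm_min, lfc_bound, min_raw_mean) >= 0))
  m_cpm <- !is.na(de$controlCPM) & de$controlCPM > cpm_min
  m_lfc <- !is.na(de$log2FoldChange) & abs(de$log2FoldChange) <= lfc_bound
  m_raw <- !is.na(de$rawMean) & de$rawMean >= min_raw_mean
  keep <- m_cpm & m_lfc & m_raw
  list(de = de[keep, , drop = FALSE], keep = keep,
       tallies = c(excluded_cpm = sum(!m_cpm),
                   excluded_lfc = sum(!m_lfc),
                   excluded_raw_mean = sum(!m_raw),
                   retained = sum(keep)))
}

#' Write a DE result as TSV with the conventional column order
#' @param de a `de_result`.
#' @param path output path.
#' @export
write_de_result <- function(de, path) {
  cols <- c("gene_id", "baseMean", "log2FoldChange", "lfcSE", "stat",
            "pvalue", "padj")
  write_tsv_plain(de[, c(cols, setdiff(names(de), cols))], path)
}
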