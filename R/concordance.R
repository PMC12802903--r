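## Downstream comparative statistics: exon/intron concordance, set overlap,
## gene-set shift, cross-genotype fold-change regression, variable-gene PCA.

#' Exon/intron fold-change concordance
#'
#' Transcriptional changes move exonic and intronic (pre-mRNA) reads
#' together; purely post-transcriptional changes move exonic reads only.
#' This compares paired exon and intron log2 fold changes over the shared
#' gene universe: Pearson R-squared, per-quadrant counts, the overlap of DE
#' calls (padj below `alpha` on each axis, same direction) with Fisher's
#' exact test against the shared universe, and a per-gene regulation class
#' from [classify_regulation()].
#'
#' @param de_exon,de_intron `de_result`s over a shared gene universe
#'   (already filtered as desired).
#' @param alpha DE-call threshold on padj (default 0.05).
#' @return list of class `concordance_report`: n, r_squared, quadrants
#'   (2x2 table of exon/intron fold-change signs), overlap (per direction:
#'   counts and Fisher p), genes (per-gene table with classification).
#' @export
exon_intron_concordance <- function(de_exon, de_intron, alpha = 0.05) {
  shared <- intersect(de_exon$gene_id, de_intron$gene_id)
  ex <- de_exon[match(shared, de_exon$gene_id), ]
  it <- de_intron[match(shared, de_intron$gene_id), ]
  ok <- is.finite(ex$log2FoldChange) & is.finite(it$log2FoldChange)
  ex <- ex[ok, ]; it <- it[ok, ]
  if (nrow(ex) < 3L) stop("fewer than 3 shared genes with finite fold changes")
  x <- ex$log2FoldChange; y <- it$log2FoldChange
  r2 <- stats::cor(x, y)^2
  quadrants <- table(exon = factor(ifelse(x >= 0, "up", "down"),
                                   c("down", "up")),
                     intron = factor(ifelse(y >= 0, "up", "down"),
                                     c("down", "up")))
  overlap <- lapply(c(up = 1, down = -1), function(dir) {
    a <- !is.na(ex$padj) & ex$padj < alpha & sign(x) == dir
    b <- !is.na(it$padj) & it$padj < alpha & sign(y) == dir
    fo <- fisher_overlap(ex$gene_id[a], ex$gene_id[b], ex$gene_id)
    list(n_exon = sum(a), n_intron = sum(b), n_both = sum(a & b),
         odds_ratio = fo$odds_ratio, p = fo$p)
  })
  genes <- data.frame(gene_id = ex$gene_id, exon_lfc = x, intron_lfc = y,
                      class = classify_regulation(x, y),
                      stringsAsFactors = FALSE)
  structure(list(n = nrow(ex), r_squared = r2, quadrants = quadrants,
                 overlap = overlap, genes = genes),
            class = "concordance_report")
}

#' Classify genes as transcriptionally or post-transcriptionally regulated
#'
#' Nearest-hypothesis rule on the (exon, intron) fold-change pair: a
#' transcriptional change predicts intron log2FC equal to the exon log2FC,
#' a post-transcriptional change predicts intron log2FC of zero. A gene is
#' called `transcriptional` when its intron fold change is closer to the
#' exon fold change than to zero, `post_transcriptional` otherwise (ties go
#' to transcriptional).
#'
#' @param exon_lfc,intron_lfc numeric vectors of paired log2 fold changes.
#' @return character vector of classes.
#' @export
classify_regulation <- function(exon_lfc, intron_lfc) {
  ifelse(abs(intron_lfc - exon_lfc) <= abs(intron_lfc),
         "transcriptional", "post_transcriptional")
}

#' Fisher's exact test for gene-set overlap
#'
#' Builds the 2x2 membership table of two sets against a finite universe
#' and reports the two-sided exact p (hypergeometric summation) and the
#' conditional odds-ratio estimate.
#'
#' @param setA,setB character vectors of gene ids (subsets of `universe`).
#' @param universe character vector of all eligible gene ids.
#' @return list: table, odds_ratio, p.
#' @export
fisher_overlap <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("both sets must be subsets of the universe")
  a <- universe %in% setA
  b <- universe %in% setB
  tab <- table(inA = factor(a, c(TRUE, FALSE)),
               inB = factor(b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Welch t-test for a fold-change shift between two gene sets
#'
#' Unpaired unequal-variance t-test on the log2 fold changes of two
#' non-overlapping gene sets (e.g. epithelial vs mesenchymal programs).
#'
#' @param de a `de_result` containing all genes of both sets.
#' @param setA,setB character vectors of gene ids, each of size >= 2.
#' @param var_equal use the pooled-variance variant instead of Welch.
#' @return list: mean_A, mean_B, t, df, p.
#' @export
geneset_shift <- function(de, setA, setB, var_equal = FALSE) {
  if (length(intersect(setA, setB))) stop("gene sets must not overlap")
  if (length(setA) < 2L || length(setB) < 2L)
    stop("both sets need >= 2 genes")
  lfc <- stats::setNames(de$log2FoldChange, de$gene_id)
  missing <- setdiff(c(setA, setB), de$gene_id)
  if (length(missing)) stop("genes missing from DE result")
  tt <- stats::t.test(lfc[setA], lfc[setB], var.equal = var_equal)
  list(mean_A = mean(lfc[setA]), mean_B = mean(lfc[setB]),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cross-contrast fold-change regression
#'
#' Ordinary least squares of one contrast's log2 fold changes on another's
#' (e.g. homozygous-vs-control on heterozygous-vs-control), over shared
#' genes with finite fold changes and raw mean counts of at least
#' `min_raw_mean` in both results. Reports slope, intercept, a t-based 95%
#' confidence interval for the slope, and Pearson R-squared.
#'
#' @param de_x,de_y `de_result`s; x is the predictor contrast.
#' @param min_raw_mean expression filter applied to both (default 50).
#' @return list of class `regression_result`: slope, intercept, ci (length
#'   2), r_squared, n.
#' @export
fc_regression <- function(de_x, de_y, min_raw_mean = 50) {
  shared <- intersect(de_x$gene_id, de_y$gene_id)
  dx <- de_x[match(shared, de_x$gene_id), ]
  dy <- de_y[match(shared, de_y$gene_id), ]
  ok <- is.finite(dx$log2FoldChange) & is.finite(dy$log2FoldChange) &
    dx$rawMean >= min_raw_mean & dy$rawMean >= min_raw_mean
  if (sum(ok) < 3L) stop("fewer than 3 shared genes after filtering")
  x <- dx$log2FoldChange[ok]; y <- dy$log2FoldChange[ok]
  if (stats::var(x) == 0) stop("zero-variance predictor fold changes")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 ci = as.numeric(ci),
                 r_squared = summary(fit)$r.squared, n = sum(ok)),
            class = "regression_result")
}

#' PCA on the most variable genes
#'
#' A compact re-expression of the standard single-cell-style preprocessing:
#' per-sample total-count scaling to 1e4 followed by log1p, gene ranking by
#' log-count variance, z-scaling of the top `n_variable` genes with values
#' clipped at |z| <= 10, then PCA retaining (number of samples - 1)
#' components.
#'
#' @param cm a [count_matrix] (>= 3 samples).
#' @param n_variable number of variable genes (default 2000; clamped with a
#'   warning when the matrix has fewer genes).
#' @return list of class `pca_result`: scores (samples x components),
#'   variance_explained, variable_genes.
#' @export
variable_gene_pca <- function(cm, n_variable = 2000L) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (ncol(counts) < 3L) stop("PCA needs >= 3 samples")
  if (n_variable > nrow(counts)) {
    warning("n_variable exceeds gene count; clamping")
    n_variable <- nrow(counts)
  }
  tot <- colSums(counts)
  if (any(tot == 0)) stop("zero-total sample")
  lognorm <- log1p(sweep(counts, 2L, tot, "/") * 1e4)
  v <- apply(lognorm, 1L, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_variable)]
  m <- lognorm[top, , drop = FALSE]
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - rowMeans(m)) / ifelse(sdv == 0, 1, sdv)
  z <- pmin(pmax(z, -10), 10)
  k <- ncol(counts) - 1L
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE, rank. = k)
  ve <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  structure(list(scores = pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE],
                 variance_explained = ve[seq_len(min(k, length(ve)))],
                 variable_genes = rownames(counts)[top]),
            class = "pca_result")
}
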