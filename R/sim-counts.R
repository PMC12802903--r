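#' Construct a count matrix container
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @param meta data frame with columns sample_id, group and optionally
#'   cohort; one row per column of `counts`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, meta) {
  stopifnot(is.matrix(counts), ncol(counts) == nrow(meta),
            all(c("sample_id", "group") %in% names(meta)))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(meta$sample_id))
    stop("gene and sample ids must be unique")
  colnames(counts) <- meta$sample_id
  if (is.null(meta$cohort)) meta$cohort <- "cohort1"
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (groups: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$group), collapse = ", ")))
  invisible(x)
}

#' Simulate exon and intron count matrices with planted ground truth
#'
#' Genes are partitioned into a TF-target set (transcriptional repression:
#' the planted log2 fold change applies to exon and intron counts alike),
#' per-family miRNA-target sets (post-transcriptional derepression: exon
#' counts only, intron truth is exactly 0), and a null remainder. Counts are
#' drawn NB(mean = baseline x library factor x 2^(true log2FC), dispersion
#' from the mean-dependent trend `a0 + a1/mu`). 3' UTR lengths are assigned
#' here (log-normal, inflated for miRNA targets) so that the optional
#' length-dependent fold-change mode can act on them; a prediction table with
#' simulated context scores and conservation flags is returned alongside.
#'
#' Each output object draws from its own named RNG stream derived from the
#' master seed, so e.g. regenerating reads never perturbs the count matrices.
#'
#' @param config a [sim_config()].
#' @return list with elements `exon` and `intron` ([count_matrix]s sharing
#'   gene and sample ids), `truth` (per-gene data frame: gene_id, set,
#'   family, utr_length, context_score, conserved, and per non-control group
#'   `true_exon_lfc_<g>` / `true_intron_lfc_<g>`), `predictions` (a target
#'   prediction table: gene_id, family, context_score, conserved) and
#'   `mirna_truth` (per-miRNA true abundance per group).
#' @export
simulate_counts <- function(config) {
  cfg <- validate_sim_config(config)
  G <- cfg$n_genes
  genes <- sprintf("gene%05d", seq_len(G))
  groups <- rep(cfg$groups, each = cfg$n_per_group)
  meta <- data.frame(
    sample_id = paste0(groups, "_", sequence(rep(cfg$n_per_group,
                                                 length(cfg$groups)))),
    group = groups, cohort = "cohort1", stringsAsFactors = FALSE)

  # --- gene structure stream: baselines, set membership, scores ---
  set.seed(stream_seed(cfg$seed, "genes"))
  base_exon <- stats::rlnorm(G, cfg$baseline_meanlog, cfg$baseline_sdlog)
  # planted miRNA-target sets belong to the families whose abundance shifts
  # (derepression follows miRNA loss); if no family shifts, split across all
  mf <- cfg$mirna_families[!cfg$mirna_families$is_spike_in, , drop = FALSE]
  fc_cols <- grep("^fc_", names(mf), value = TRUE)
  shifted <- if (length(fc_cols))
    apply(mf[, fc_cols, drop = FALSE] != 1, 1L, any) else rep(FALSE, nrow(mf))
  fams <- unique(mf$family[shifted])
  if (length(fams) == 0L) fams <- unique(mf$family)
  n_tf <- round(cfg$tf_target_fraction * G)
  n_mir_tot <- round(cfg$mir_target_fraction * G)
  n_mir <- rep(n_mir_tot %/% length(fams), length(fams))
  if ((r <- n_mir_tot - sum(n_mir)) > 0) n_mir[seq_len(r)] <- n_mir[seq_len(r)] + 1L
  idx <- sample.int(G)
  set <- rep(NA_character_, G)
  family <- rep(NA_character_, G)
  if (n_tf > 0) set[idx[seq_len(n_tf)]] <- "tf_target"
  off <- n_tf
  for (i in seq_along(fams)) {
    if (n_mir[i] > 0) {
      ii <- idx[off + seq_len(n_mir[i])]
      set[ii] <- "mir_target"
      family[ii] <- fams[i]
    }
    off <- off + n_mir[i]
  }
  is_mir <- !is.na(set) & set == "mir_target"
  context_score <- rep(NA_real_, G)
  context_score[is_mir] <- -abs(stats::rnorm(sum(is_mir), 0.30, 0.15)) - 0.02
  conserved <- rep(NA, G)
  if (cfg$mir_effect_scaling == "score") {
    # conservation tracks prediction confidence so higher-confidence subsets
    # carry larger planted effects
    conserved[is_mir] <- context_score[is_mir] <=
      stats::median(context_score[is_mir])
  } else {
    conserved[is_mir] <- stats::runif(sum(is_mir)) < 0.5
  }

  # --- UTR stream ---
  set.seed(stream_seed(cfg$seed, "utr"))
  utr <- stats::rlnorm(G, cfg$utr_meanlog, cfg$utr_sdlog)
  utr[is_mir] <- utr[is_mir] * (1 + cfg$utr_length_bias)
  utr <- pmax(1L, as.integer(round(utr)))

  # --- true effects ---
  eff_exon <- numeric(G)
  eff_intron <- numeric(G)
  tf <- !is.na(set) & set == "tf_target"
  eff_exon[tf] <- cfg$tf_log2fc
  eff_intron[tf] <- cfg$tf_log2fc
  if (cfg$mir_effect_scaling == "score" && any(is_mir)) {
    sc <- abs(context_score[is_mir])
    eff_exon[is_mir] <- cfg$mir_log2fc * sc / stats::median(sc)
  } else {
    eff_exon[is_mir] <- cfg$mir_log2fc
  }
  bg <- is.na(set)
  if (cfg$transcriptome_effect_sd > 0 && any(bg)) {
    set.seed(stream_seed(cfg$seed, "transcriptome_program"))
    prog <- stats::rnorm(sum(bg), 0, cfg$transcriptome_effect_sd)
    eff_exon[bg] <- eff_exon[bg] + prog
    eff_intron[bg] <- eff_intron[bg] + prog
  }
  if (cfg$utr_effect_log2fc != 0) {
    l2u <- log2(utr)
    eff_exon <- eff_exon + cfg$utr_effect_log2fc * (l2u - mean(l2u))
  }

  # --- library sizes (one stream; shared across exon and intron) ---
  set.seed(stream_seed(cfg$seed, "libsizes"))
  lib_tot <- stats::runif(nrow(meta), cfg$library_size_range[1L],
                          cfg$library_size_range[2L])
  lib_factor <- lib_tot / mean(cfg$library_size_range)

  scale_g <- unname(cfg$group_effect_scale[meta$group])
  a0 <- cfg$nb_dispersion_params[[1L]]
  a1 <- cfg$nb_dispersion_params[[2L]]

  draw <- function(base, eff, stream) {
    set.seed(stream_seed(cfg$seed, stream))
    mu <- outer(base, lib_factor) * 2^outer(eff, scale_g)
    alpha <- a0 + a1 / pmax(mu, 1e-8)
    k <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / pmax(alpha, 1e-12)),
                nrow = nrow(mu))
    rownames(k) <- genes
    k
  }
  exon <- draw(base_exon, eff_exon, "exon_counts")
  intron <- draw(base_exon * cfg$intron_fraction, eff_intron, "intron_counts")

  truth <- data.frame(gene_id = genes, set = set, family = family,
                      utr_length = utr, context_score = context_score,
                      conserved = conserved, stringsAsFactors = FALSE)
  for (g in cfg$groups[-1L]) {
    s <- cfg$group_effect_scale[[g]]
    truth[[paste0("true_exon_lfc_", g)]] <- eff_exon * s
    truth[[paste0("true_intron_lfc_", g)]] <- eff_intron * s
  }
  preds <- truth[is_mir, c("gene_id", "family", "context_score", "conserved")]
  rownames(preds) <- NULL

  mt <- cfg$mirna_families[!cfg$mirna_families$is_spike_in, ]
  mirna_truth <- data.frame(mirna_id = mt$mirna_id, family = mt$family,
                            stringsAsFactors = FALSE)
  mirna_truth[[paste0("abundance_", cfg$groups[1L])]] <- mt$baseline
  for (g in cfg$groups[-1L])
    mirna_truth[[paste0("abundance_", g)]] <- mt$baseline * mt[[paste0("fc_", g)]]

  list(exon = count_matrix(exon, meta),
       intron = count_matrix(intron, meta),
       truth = truth, predictions = preds, mirna_truth = mirna_truth)
}

#' Materialize the 3' UTR length table from planted truth
#'
#' Lengths are assigned during [simulate_counts()] (log-normal for
#' nontargets, multiplied by `1 + utr_length_bias` for miRNA targets); this
#' simply extracts the two-column table written to disk for the pipeline.
#'
#' @param config a [sim_config()] (unused beyond validation; kept so the
#'   generator surface mirrors the other simulators).
#' @param truth the `truth` element returned by [simulate_counts()].
#' @return data frame with columns gene_id, utr_length.
#' @export
simulate_utr_table <- function(config, truth) {
  validate_sim_config(config)
  stopifnot(all(c("gene_id", "utr_length") %in% names(truth)))
  data.frame(gene_id = truth$gene_id, utr_length = truth$utr_length,
             stringsAsFactors = FALSE)
}

#' Write generator outputs to a directory as plain-text files
#'
#' Counts, truth, predictions and UTR table as TSV; config as YAML.
#' @param sim result of [simulate_counts()].
#' @param config the [sim_config()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_outputs <- function(sim, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("exon", "intron")) {
    m <- sim[[what]]$counts
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write_tsv_plain(df, file.path(dir, paste0(what, "_counts.tsv")))
  }
  write_tsv_plain(sim$exon$meta, file.path(dir, "samples.tsv"))
  write_tsv_plain(sim$truth, file.path(dir, "truth.tsv"))
  write_tsv_plain(sim$predictions, file.path(dir, "predictions.tsv"))
  write_tsv_plain(simulate_utr_table(config, sim$truth),
                  file.path(dir, "utr_lengths.tsv"))
  write_sim_config(config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Save / load a simulation configuration as YAML
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$mirna_families <- as.list(cfg$mirna_families)
  cfg$group_effect_scale <- as.list(cfg$group_effect_scale)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$mirna_families <- as.data.frame(cfg$mirna_families,
                                      stringsAsFactors = FALSE)
  cfg$group_effect_scale <- unlist(cfg$group_effect_scale)
  cfg$nb_dispersion_params <- unlist(cfg$nb_dispersion_params)
  cfg$library_size_range <- unlist(cfg$library_size_range)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}
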