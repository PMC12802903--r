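#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the pituitary study design this package was built around: a wild-type
#' group plus heterozygous and homozygous knock-in groups with 4 biological
#' replicates each, a set of transcription-factor (TF) target genes planted
#' with transcriptional repression (affecting exon and intron counts alike),
#' and sets of miRNA target genes planted with post-transcriptional
#' derepression (exon counts only). miRNA target genes have 3' UTRs that are
#' longer on average than nontargets, reproducing the length confound that
#' motivates UTR-length-matched nontarget sampling.
#'
#' @param n_genes number of genes.
#' @param n_per_group biological replicates per group.
#' @param groups group labels; the first is the control/reference group.
#' @param group_effect_scale named multiplier of all planted log2 fold
#'   changes per group (control must be 0). The default `hom = 1.1` plants a
#'   slightly larger effect in the homozygous group, as seen in paired
#'   het/hom fold-change regressions.
#' @param nb_dispersion_params c(a0, a1): mean-dependent NB dispersion trend
#'   `alpha(mu) = a0 + a1 / mu`.
#' @param library_size_range pair of positive library totals; each sample's
#'   total is drawn uniformly in this range and shared between its exon and
#'   intron matrices (same library).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   exon mean counts.
#' @param intron_fraction intron baseline as a fraction of exon baseline
#'   (intronic reads are sparse; free parameter, default 0.2).
#' @param tf_target_fraction,tf_log2fc fraction of genes planted as TF
#'   targets and their (typically negative) log2 fold change, applied to exon
#'   AND intron counts.
#' @param mir_target_fraction,mir_log2fc fraction of genes planted as miRNA
#'   targets (split evenly across families) and their log2 fold change,
#'   applied to exon counts only.
#' @param mir_effect_scaling `"uniform"` (all targets get `mir_log2fc`) or
#'   `"score"` (effect scales with the magnitude of the simulated context
#'   score, so higher-confidence predictions carry larger effects).
#' @param utr_length_bias multiplicative 3' UTR length inflation for miRNA
#'   target genes (>= 0); 1 doubles the median target length.
#' @param utr_meanlog,utr_sdlog log-normal parameters of nontarget 3' UTR
#'   lengths (nt).
#' @param transcriptome_effect_sd standard deviation of a widespread
#'   transcriptional program: genes outside the planted sets receive a
#'   N(0, sd) log2 fold change applied to exon AND intron counts (scaled per
#'   group like every other effect). Emulates the genome-wide downstream
#'   program a derepressed transcription factor sets off; set to 0 for null
#'   simulations.
#' @param utr_effect_log2fc optional slope of a UTR-length-dependent exon
#'   log2 fold change, in log2-FC units per log2(length) unit centred on the
#'   mean; used to study the length confound. Default 0.
#' @param mirna_families data frame describing simulated mature miRNAs
#'   (columns mirna_id, family, sequence, baseline, plus one fold-change
#'   column per non-control group named `fc_<group>`); `NULL` uses
#'   [default_mirna_families()].
#' @param spikein_proportion total proportion of small-RNA reads drawn from
#'   spike-in species.
#' @param subq30_read_fraction fraction of simulated reads given one sub-Q30
#'   base (all other bases are Q37), to exercise the quality filter.
#' @param read_length simulated small-RNA read length (nt).
#' @param seed master seed; every stream derives from it via [stream_seed()].
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_per_group = 4L,
                       groups = c("wt", "het", "hom"),
                       group_effect_scale = c(wt = 0, het = 1, hom = 1.1),
                       nb_dispersion_params = c(a0 = 0.02, a1 = 2),
                       library_size_range = c(8e5, 1.2e6),
                       baseline_meanlog = log(200),
                       baseline_sdlog = 1.3,
                       intron_fraction = 0.2,
                       tf_target_fraction = 0.05,
                       tf_log2fc = -1,
                       mir_target_fraction = 0.1,
                       mir_log2fc = log2(1.25),
                       mir_effect_scaling = c("uniform", "score"),
                       transcriptome_effect_sd = 0.75,
                       utr_length_bias = 1,
                       utr_meanlog = log(600),
                       utr_sdlog = 0.8,
                       utr_effect_log2fc = 0,
                       mirna_families = NULL,
                       spikein_proportion = 0.02,
                       subq30_read_fraction = 0.02,
                       read_length = 50L,
                       seed = 1L) {
  mir_effect_scaling <- match.arg(mir_effect_scaling)
  if (is.null(mirna_families)) mirna_families <- default_mirna_families(groups)
  cfg <- list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    groups = groups, group_effect_scale = group_effect_scale,
    nb_dispersion_params = nb_dispersion_params,
    library_size_range = library_size_range,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    intron_fraction = intron_fraction,
    tf_target_fraction = tf_target_fraction, tf_log2fc = tf_log2fc,
    mir_target_fraction = mir_target_fraction, mir_log2fc = mir_log2fc,
    mir_effect_scaling = mir_effect_scaling,
    transcriptome_effect_sd = transcriptome_effect_sd,
    utr_length_bias = utr_length_bias,
    utr_meanlog = utr_meanlog, utr_sdlog = utr_sdlog,
    utr_effect_log2fc = utr_effect_log2fc,
    mirna_families = mirna_families,
    spikein_proportion = spikein_proportion,
    subq30_read_fraction = subq30_read_fraction,
    read_length = as.integer(read_length),
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L || cfg$n_per_group < 1L)
    stop("configuration error: n_genes and n_per_group must be positive")
  if (length(cfg$groups) < 2L || anyDuplicated(cfg$groups))
    stop("configuration error: need >= 2 distinct group labels")
  if (!all(cfg$groups %in% names(cfg$group_effect_scale)))
    stop("configuration error: group_effect_scale must name every group")
  if (cfg$group_effect_scale[[cfg$groups[1L]]] != 0)
    stop("configuration error: control group effect scale must be 0")
  fr <- c(cfg$tf_target_fraction, cfg$mir_target_fraction)
  if (any(fr < 0) || sum(fr) > 1)
    stop("configuration error: planted-set fractions must be >= 0 and sum <= 1")
  if (any(cfg$library_size_range <= 0) || length(cfg$library_size_range) != 2L)
    stop("configuration error: library_size_range must be two positive totals")
  if (any(cfg$nb_dispersion_params < 0))
    stop("configuration error: dispersion trend parameters must be >= 0")
  if (cfg$utr_length_bias < 0)
    stop("configuration error: utr_length_bias must be >= 0")
  if (cfg$transcriptome_effect_sd < 0)
    stop("configuration error: transcriptome_effect_sd must be >= 0")
  if (cfg$intron_fraction <= 0)
    stop("configuration error: intron_fraction must be positive")
  if (any(cfg$mirna_families$baseline <= 0, na.rm = TRUE))
    stop("configuration error: miRNA baseline abundances must be positive")
  cfg
}

#' Default simulated mature miRNA table
#'
#' The miR-200 superfamily mature sequences (standard miRBase mouse
#' sequences) plus a panel of abundant, stable miRNAs (representative mature
#' sequences of well-known conserved miRNAs) and two synthetic spike-in
#' species. Non-control groups carry strong miR-200a/b down-shifts (5-7
#' fold), mirroring loss of the miR-200 loci under elevated ZEB1, while the
#' remaining miRNAs are unchanged. The stable panel deliberately outnumbers
#' the shifted species so that median-of-ratios normalization of the
#' quantified counts anchors on unchanged miRNAs, as it does in real
#' libraries where most of hundreds of miRNAs are stable.
#'
#' @param groups group labels; the first is control.
#' @return data frame with columns mirna_id, family, sequence, is_spike_in,
#'   baseline, and `fc_<group>` for each non-control group.
#' @export
default_mirna_families <- function(groups = c("wt", "het", "hom")) {
  tab <- data.frame(
    mirna_id = c("miR-200b-3p", "miR-200c-3p", "miR-429-3p",
                 "miR-200a-3p", "miR-141-3p",
                 "miR-26a-5p", "miR-125b-5p", "let-7a-5p", "miR-124-3p",
                 "miR-7a-5p", "miR-9-5p", "miR-21a-5p", "miR-22-3p",
                 "miR-30d-5p", "miR-143-3p", "miR-148a-3p", "miR-152-3p",
                 "miR-181a-5p", "miR-375-3p",
                 "spike-synth-1", "spike-synth-2"),
    family = c("miR-200b/c/429", "miR-200b/c/429", "miR-200b/c/429",
               "miR-200a/141", "miR-200a/141",
               "miR-26", "miR-125", "let-7", "miR-124",
               "miR-7", "miR-9", "miR-21", "miR-22",
               "miR-30", "miR-143", "miR-148", "miR-148",
               "miR-181", "miR-375",
               "spike", "spike"),
    sequence = c("UAAUACUGCCUGGUAAUGAUGA",
                 "UAAUACUGCCGGGUAAUGAUGGA",
                 "UAAUACUGUCUGGUAAAACCGU",
                 "UAACACUGUCUGGUAACGAUGU",
                 "UAACACUGUCUGGUAAAGAUGG",
                 "UUCAAGUAAUCCAGGAUAGGCU",
                 "UCCCUGAGACCCUAACUUGUGA",
                 "UGAGGUAGUAGGUUGUAUAGUU",
                 "UAAGGCACGCGGUGAAUGCCAA",
                 "UGGAAGACUAGUGAUUUUGUUGU",
                 "UCUUUGGUUAUCUAGCUGUAUGA",
                 "UAGCUUAUCAGACUGAUGUUGA",
                 "AAGCUGCCAGUUGAAGAACUGU",
                 "UGUAAACAUCCCCGACUGGAAG",
                 "UGAGAUGAAGCACUGUAGCUCA",
                 "UCAGUGCACUACAGAACUUUGU",
                 "UCAGUGCAUGACAGAACUUGGG",
                 "AACAUUCAACGCUGUCGGUGAGU",
                 "UUUGUUCGUUCGGCUCGCGUGA",
                 "ACGUACGGUUCAGACCAUGGAC",
                 "GGACUUACCGGAUCAUGGAAGU"),
    is_spike_in = c(rep(FALSE, 19L), TRUE, TRUE),
    baseline = c(3000, 800, 500, 2500, 900,
                 4000, 6000, 5000, 150,
                 2500, 800, 7000, 3000, 1500, 1200, 2000, 600,
                 1800, 9000, NA, NA),
    stringsAsFactors = FALSE)
  down <- c(rep(TRUE, 5L), rep(FALSE, 14L), NA, NA)
  for (g in groups[-1L]) {
    fc <- ifelse(is.na(down), NA, ifelse(down, 1 / 6, 1))
    # slightly stronger loss in later (e.g. homozygous) groups
    fc[down %in% TRUE] <- fc[down %in% TRUE] /
      (1 + 0.2 * (match(g, groups) - 2))
    tab[[paste0("fc_", g)]] <- fc
  }
  tab
}
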