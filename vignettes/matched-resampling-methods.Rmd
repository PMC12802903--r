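---
title: "Quantifying miRNA target derepression with UTR-length-matched resampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA target derepression with UTR-length-matched resampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirderep)
```

## The problem

When a miRNA family is lost or strongly reduced, its predicted targets are
derepressed: their mRNA levels rise, typically by small amounts (median
effects of 1.1-1.3-fold even for high-confidence targets). Detecting such a
shift in a differential-expression experiment means comparing the log2
fold-change distribution of a predicted target set against some background.
The naive background — all non-targets — is confounded: genes with long 3'
UTRs are more likely to carry predicted sites *and* respond differently to
many perturbations, so an apparent "target effect" can be a 3'-UTR-length
effect in disguise.

`mirderep` implements the matched-resampling estimator that removes this
confound, together with the supporting pipeline: a compact two-group
negative-binomial (NB) differential-expression engine, exact-prefix
quantification of mature miRNAs from small-RNA-seq reads, merged exon/intron
annotation for separating transcriptional from post-transcriptional changes,
and a synthetic-data generator that plants all of these effect structures so
the entire pipeline can be validated against known truth.

## The matched-resampling statistic

Given a differential-expression table, a target prediction table (gene,
miRNA family, cumulative context score, conservation flag) and a table of 3'
UTR lengths:

1. Restrict to the analysis universe: genes with finite log2 fold changes,
   at least 50 raw read counts on average, and a known UTR length.
2. Assign every gene in the universe to one of 10 equal-count
   (quantile) UTR-length bins.
3. Build three target sets for the focal family: *all* predicted targets,
   the *conserved* subset, and the *top* 10% by most-negative cumulative
   context score. The nontarget pool is the universe minus every predicted
   target of the focal family (and of any excluded families).
4. For each target, draw one nontarget uniformly *with replacement* from the
   target's UTR bin. The cohort therefore has exactly the target set's bin
   histogram — length matching is by construction, not by reweighting.
5. Report the difference of median log2 fold changes and a Mann-Whitney
   p-value between the two samples.
6. Repeat the draw 21 times; report the mean difference in medians and the
   median p-value across replicates.

Both orientations of the median difference are carried explicitly:
`repression` (nontarget minus target median) and `derepression` (target
minus nontarget), because the two conventions coexist in practice and a
silent sign flip is the easiest mistake to make with this statistic. Plots
and the worked examples use the derepression orientation (positive when a
repressing miRNA has been lost).

Design choices worth recording:

* **Quantile bins.** "10 bins" does not define boundaries; equal-count bins
  guarantee that no bin is empty and that bin membership is invariant to the
  length distribution's shape. Ties are broken by gene id, making the
  assignment order-invariant. An equal-width variant was considered and
  rejected: with log-normal-like length distributions most equal-width bins
  are nearly empty.
* **Nontarget pool for the conserved/top sets.** The pool always excludes
  *all* predicted targets of the family, not only the subset being scored —
  a "conserved-set nontarget" that is itself a weak predicted target would
  dilute the contrast.
* **Sampling with replacement** means one nontarget can serve several
  targets in a replicate; this is the only reading consistent with
  independent per-target draws from small bins.
* **Mann-Whitney sidedness** defaults to two-sided (conservative; a
  one-sided alternative is available as an argument).
* **Replicate seeds** derive from the master seed through a named counter
  stream, so replicate *r* is reproducible in isolation and the replicate
  count can change without reshuffling earlier replicates.
* The replicate count must be odd so the median p-value is an observed
  value.

Because the statistic is a *difference* between target and matched-nontarget
medians computed on the same DE table, it is invariant to any global shift
of the log2 fold changes — including the composition shifts that
median-of-ratios normalization exhibits when strong one-directional
expression changes are present. The validation suite exploits this: the
statistic stays unbiased in regimes where absolute fold-change estimates
drift by several hundredths.

## The NB differential-expression engine

The engine is deliberately a compact two-group NB fitter, not a
re-implementation of the full empirical-Bayes machinery of the established
tools:

* **Size factors**: median-of-ratios over genes with nonzero counts in all
  samples (`factor_s = median_g count_gs / geomean_g`).
* **Dispersion**: per-gene method-of-moments on normalized counts pooled
  within groups, floored at 1e-8, then blended 50/50 with an OLS-fitted
  mean-dependent trend `alpha(mu) = a0 + a1 / mu`. The blend stabilizes
  small-replicate moment estimates; it is simpler and more transparent than
  full empirical-Bayes shrinkage, at the cost of slightly noisier
  dispersions.
* **Wald test**: per-gene NB GLM with log link, group indicator and
  log-size-factor offsets, fit by IRLS vectorized across genes (all genes
  iterate simultaneously; convergence at relative coefficient change below
  1e-8 or 100 iterations). The standard error comes from the expected
  information at convergence; the p-value is two-sided normal. No
  fold-change shrinkage is applied.
* **Degenerate genes**: a gene with zero counts throughout one group gets a
  signed infinite log2 fold change with NA statistics; the standard plot
  filter (|log2FC| <= 5) removes it. No pseudocounts are added anywhere.
* **Known behaviour**: with 4-6 replicates per group the normal reference
  and dispersion-estimation noise make the test mildly anticonservative
  (null rejection at the 5% level measures ~5.5-6%). The validation suite
  measures this directly; analyses that depend on calibration should note
  it. Cook's-style outlier handling and independent filtering are
  intentionally absent.

The standard analysis filters are exposed as three independent masks:
control-sample mean CPM strictly above 1, |log2FC| at most 5 (inclusive
bounds), and raw mean count at least 50 (inclusive).

## Small-RNA quantification

Reads are expected to be insert + 3'-adapter, where the insert is 4
randomized nucleotides + mature miRNA + 4 randomized nucleotides (the
randomized positions come from the adapters and reduce ligation bias).
The pipeline:

1. **Quality filter**: keep reads where every base (a configurable
   fraction) has Phred quality >= 30, inclusive.
2. **Adapter trim**: find the leftmost exact match of the first 8 nt of the
   3'-adapter invariant, cut there, then strip the randomized flanks. Reads
   with no adapter hit or an implausibly short insert are dropped and
   tallied, never silently lost.
3. **Exact-prefix match**: the read's first k nt (19 by default, 18 for
   older library chemistry; a single parameter) must equal a dictionary
   entry's first k nt with no mismatches. Dictionary entries whose full
   sequences differ but share a k-prefix are rejected at load time; entries
   with identical full sequences (paralogs yielding the same mature miRNA)
   must be explicitly collapsed into one id — silent double counting is
   never an option.
4. **Accounting**: matched + unmatched + spike-removed + quality-filtered =
   reads in, enforced as an invariant at every stage.
5. **CPM**: normalized count divided by the sample's normalized total,
   times 1e6 — the only reading of "per million" that makes each sample sum
   to exactly 1e6.

## Exon/intron annotation and concordance

Transcriptional changes move exonic and intronic (pre-mRNA) reads together;
purely post-transcriptional changes move exonic reads only. To measure this,
all transcripts of a gene are merged: the exon union is the interval union
of all exons, and the intron union is the gene span (minimum exon start to
maximum exon end) minus the exon union — all introns combined into one
annotation. Coordinates are converted from GTF's 1-based inclusive to
0-based half-open at the I/O boundary and kept half-open everywhere else.

The accompanying union-mode counter assigns a read to a gene when any
aligned block overlaps the gene's interval set and the strand rule passes
(ignore / same-strand / opposite-strand, matching the common `-s 0/1/2`
convention); reads touching two genes' sets are discarded as ambiguous. It
is a validation instrument — exact on small problems, checked against a
per-base brute-force oracle — not a production counter; paired-end reads and
multimapper weighting are out of scope. Per-gene regulation calls use a
nearest-hypothesis rule: a gene is "transcriptional" when its intron fold
change is closer to its exon fold change than to zero.

## The synthetic-data generator

The generator emulates the structure of a two-to-three-genotype bulk
RNA-seq + small-RNA-seq study of a tissue where a miRNA-transcription-factor
double-negative feedback loop has been perturbed:

* a *TF-target program*: a gene set with a common negative log2 fold change
  applied to exon and intron counts alike (transcriptional repression);
* *miRNA-target programs*: per-family gene sets with positive log2 fold
  changes applied to exon counts only (post-transcriptional derepression),
  optionally scaled by the simulated context score so higher-confidence
  predictions carry larger effects; target sets are assigned to the miRNA
  families whose abundance shifts;
* a *widespread transcriptional program*: N(0, sd) log2 fold changes on the
  remaining genes (exons and introns), emulating the genome-wide downstream
  consequences of a derepressed transcription factor;
* a *UTR-length confound*: miRNA-target UTR lengths are inflated by
  `1 + utr_length_bias`, and an optional length-dependent fold-change slope
  can make expression changes depend on UTR length directly;
* *small-RNA reads* with randomized flanks, adapters, spike-ins at fixed
  proportions, and a configurable fraction of sub-Q30 bases;
* per-sample library sizes shared between the exon and intron matrices
  (same library), with intron baselines at 20% of exon baselines.

Counts are NB with a mean-dependent dispersion trend `a0 + a1/mu`. Defaults:
`a0 = 0.02, a1 = 2` (gene-wise dispersions typical of clean inbred-mouse
bulk RNA-seq), baseline means log-normal(log 200, 1.3), 4 replicates per
group, three groups with effect scales 0 / 1 / 1.1 so the two mutant
genotypes share a program with slightly larger magnitude in the homozygote.
Every output object draws from its own named RNG stream derived from the
master seed, so regenerating one output never perturbs another, and the
whole simulation is reproducible from (config, seed).

What the generator does **not** model: sequence-level mRNA reads or
alignment, positional/GC biases, isomiRs, imperfect target predictions (the
prediction table is the planted truth, so "all predicted targets" are all
truly responsive — real prediction tables are noisier and dilute the
signal), and any causal coupling between the simulated miRNA abundance
drop and the magnitude of target derepression (both are planted
independently). Passing validation on this generator therefore demonstrates
correctness of the *statistics*, not performance on the messier features of
real data.

## Validation problem sizes and numerical notes

The validation suite and the acceptance script run the full pipeline on
2000-gene cohorts with 4-8 replicates per group: 50 repetitions each for the
null calibration and the recovery of a planted log2(1.25) derepression; 10
repetitions for the length-confound contrast (matched vs single-bin naive
pools); a symmetric ±1/±2 grid for fold-change recovery (symmetric planting
avoids the composition bias that median-of-ratios normalization shows under
strong one-directional change); a 100-gene / 10,000-read toy annotation for
the interval engine; 100,000 reads for small-RNA accounting; and 20 seeds
for the het/hom regression with a widespread program of sd 2. The
exon/intron discrimination study uses deeper libraries (baseline mean 1000)
and 8 replicates per group: intronic reads are ~20% of exonic, and
intron-level inference at realistic precision needs that depth.

Tie-breaking and tolerance conventions are centralized: quantile-bin ties
break by gene id; Mann-Whitney uses midranks, an exact null distribution
when the samples are tie-free and `n_x * n_y <= 400`, and a tie- and
continuity-corrected normal approximation otherwise; IRLS tolerances are
relative (1e-8); dispersions are floored at 1e-8.

## Limitations

The DE engine supports exactly two groups with a single condition factor —
no covariates, no interactions, no outlier refitting. The interval counter
is single-end only. The quantifier does not tolerate mismatches, so heavily
edited or 5'-isomiR reads go uncounted. Family selection operates on
summary tables the caller assembles; it does not itself aggregate members
into families. All validation evidence comes from the generator described
above; claims about real-data performance should be calibrated accordingly.
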