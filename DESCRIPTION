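Package: mirderep
Title: miRNA Target Derepression Analysis with UTR-Length-Matched Resampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying derepression of predicted miRNA target
    sets from bulk RNA-seq, built around a 3'-UTR-length-matched nontarget
    resampling statistic. Includes a lightweight two-group negative-binomial
    Wald differential-expression engine (median-of-ratios size factors,
    moment-based dispersion with trend shrinkage), exact-prefix quantification
    of mature miRNAs from small-RNA-seq reads, merged exon/intron interval
    annotation with a union-mode read counter for exon-versus-intron
    (transcriptional versus post-transcriptional) concordance analysis, and a
    synthetic-data generator that plants known transcriptional and
    post-transcriptional effects so every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
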