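Package: ccrnet
Title: Cell-Cycle Transcriptome Quantification, Co-Expression Modules and
    Phylogenetic Signal
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for bacterial cell-cycle transcriptomics:
    replicate-aware quantification of strand-specific RNA-Seq coverage with
    dynamic-programming segmentation of the coefficient-of-variation signal
    and filtering of inconsistent (GC-biased) regions; power-law
    characterization of the expression distribution and classification of
    genes into low/bulk/high expression groups; empirical-Bayes
    negative-binomial model selection over enumerated time-course patterns to
    detect cell-cycle-regulated genes; signed weighted co-expression networks
    with topological overlap, module detection and module eigenvectors; and
    phylogenetic-signal analysis of module conservation profiles (Blomberg's
    K, standardized-effect-size MPD/MNTD) on a species tree, with gene
    persistence from reciprocal-best-hit orthology.  Includes a synthetic-data
    generator that emulates the statistical structure of such a study
    (expression strata, GC-correlated replicate inconsistency, planted
    cell-cycle programs, birth-death species trees with planted broadly
    conserved and clade-specific modules) for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
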