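Package: MBDscan
Title: Window-Based Differential Methylation Analysis for MBD-seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide differential DNA methylation analysis for
    enrichment-based methylome sequencing (MBD-seq / MiGS). Read coverage is
    summarised in fixed-width windows tiling the genome, low-coverage windows
    are removed by a Poisson false-discovery filter assuming even genomic
    coverage, and per-sample signal is deconvolved with a three-component
    Poisson mixture fitted by EM, yielding a posterior probability of
    methylation per window. A gap-tolerant scan merges methylated windows
    into per-sample segments and cross-sample candidate regions, which are
    tested for group differences with a linear mixed-effects model and
    classified as sharp yes/no or quantitative differentially methylated
    regions (DMRs). DMRs are annotated by gene-model context (promoter,
    3' end, exon, intron, intergenic, with a fixed priority) and CpG-island
    context (island, shore, shelf, open sea), and promoter DMRs are joined
    with a differential-expression table to report genes whose expression
    change is inverse to their promoter methylation change. A synthetic-data
    module plants ground-truth regions and inverse-correlated genes so that
    every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    lme4,
    lmerTest,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    Sequencing, Coverage
RoxygenNote: 7.3.3
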