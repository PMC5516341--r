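Package: methylDMR
Title: Differential Methylation Analysis for Two-Group 450K Array Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A case-control differential-methylation pipeline for Illumina
    450K-style methylation arrays: negative-control background correction,
    per-channel quantile normalisation, failed-probe / Y-chromosome /
    cross-reactive probe filtering, beta-value computation, per-CpG one-way
    ANOVA F tests with delta-beta effect sizes, threshold-based
    differentially methylated position (DMP) prioritisation, gap-chained
    differentially methylated region (DMR) calling, and hypergeometric
    gene-set over-representation analysis with Benjamini-Hochberg FDR
    control. Includes a synthetic-data generator with planted DMRs and
    ground truth, and a packaged reference DMP set from a published CD4+
    T-cell relapsing-remitting multiple sclerosis methylation study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
biocViews: DNAMethylation, DifferentialMethylation, MethylationArray,
    Epigenetics, QualityControl, GeneSetEnrichment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
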