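Package: somaticpanel
Title: Somatic Mutation Profiling for Targeted Tumor/Normal Sequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for somatic mutation analysis of deeply
    sequenced tumor/normal gene panels. Provides a Bayesian diploid genotype
    caller with Phred-scaled consensus and variant qualities, calibration of
    call-quality thresholds against orthogonal SNP-array genotypes (including
    sample-mislabel screening), germline-subtraction somatic filtering with
    polymorphism-panel removal, per-gene deleterious-mutation rate statistics,
    Sanger-validation accounting, copy-number segmentation and DNA-RNA
    concordance integration into per-sample actionability profiles, and
    expression statistics (quantile normalization, gene-set z-score
    signatures, cancer outlier profile analysis, and qPCR abundance
    normalization). A fully seeded synthetic tumor/normal cohort generator
    with recorded ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
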