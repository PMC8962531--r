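Package: VariantAgreement
Title: Analytical Validation Statistics for Clinical Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype-aware variant concordance analysis for the analytical
    validation of clinical whole-genome sequencing assays. Implements
    positive/negative percent agreement (PPA/NPA) with per-sample and pooled
    confidence intervals stratified by genomic context and variant type,
    inter-laboratory precision via the Jaccard similarity coefficient with a
    permutation test of lab equivalence, rule-based reportable-range
    construction (exon padding, site augmentation, GC/homopolymer/micro-repeat
    exclusion scanning, low-coverage flagging), quality-control threshold
    simulation (coverage downsampling, cross-sample contamination, duplicate
    injection) with a binomial genotype-likelihood caller and allele-fraction
    limit-of-detection analysis, and rule-based pharmacogenomic star-allele
    diplotype calling with multi-method concordance tabulation. A synthetic
    cohort generator with controlled per-stratum error rates provides fully
    seeded test inputs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
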