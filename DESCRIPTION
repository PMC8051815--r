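Package: varbatch
Title: Variant-Level Batch Effect Diagnostics for Case-Control Sequencing Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and adjudication of hidden variant-level batch effects
    (exome capture-kit differences in genotype quality and alternative allele
    fraction) in case/control sequencing association studies. Provides a
    read-level synthetic-cohort generator emulating a two-kit, three-center
    design with allelic capture bias, VCF/metadata input-output, sample- and
    variant-level quality control including an exact Hardy-Weinberg test,
    genotype principal component analysis with a subpopulation-clustering
    surrogate, additive logistic association (full-cohort and batch-stratified)
    with Bonferroni thresholding and batch-exclusive flagging, and per-variant
    batch diagnostics: per-kit quality-metric log2 ratios and tails, subset-PCA
    kit separation, alternative-allele-fraction bimodality, reference minor
    allele frequency concordance, and allelic capture-efficiency estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    cluster,
    mclust,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
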