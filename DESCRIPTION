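Package: alfredr
Title: Two-Hit Cancer Predisposition Gene Discovery from Paired
    Tumor-Normal Exomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the ALFRED statistical framework for testing
    Knudson's two-hit hypothesis genome-wide on paired tumor-normal exome
    cohorts. Calls per-gene allelic imbalance (putative loss of
    heterozygosity) from germline-variant allele depths using per-variant
    Fisher exact tests pooled by Fisher's method, classifies rare damaging
    germline variants (RDGVs), and tests each gene for enrichment of RDGVs
    in allelic-imbalance samples via stratified randomization within
    population-structure clusters, together with a one-tailed binomial test
    for directional loss of the wild-type allele. Includes case-control and
    tissue-specificity burden analyses, contribution-to-risk curves, and a
    synthetic paired-cohort simulator with planted two-hit genes for
    calibration and power studies.
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
    VariantAnnotation,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
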