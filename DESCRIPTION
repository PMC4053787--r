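Package: substrain
Title: Comparative Genomic and Phenotypic Analysis of Mouse Sub-Strains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing closely related inbred mouse sub-strains
    (C57BL/6J versus C57BL/6N) at the genomic and phenotypic level. Implements
    the hard-filter cascade used to call high-confidence SNP and small-indel
    differences between near-identical genomes (reference-set subtraction,
    allele-ratio and read-depth filters, codon-level consequence
    classification, strain-privacy assessment, and validation-assay
    adjudication with ledger bookkeeping), a structural-variant triage state
    machine with gene-overlap annotation and outgroup-based ancestral-event
    classification, and a multi-center phenotype comparison: per
    parameter/center/sex exact nonparametric tests, heat-map color/shade
    encoding, cross-center concordance classes, and a randomization null for
    the rate of multi-center concordance. Ships the published coding-variant
    and structural-variant tables as plain-text fixtures and includes
    synthetic-data generators for phenotype studies and variant call sets
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    jsonlite,
    IRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
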