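Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Population Structure
    for SNP-Array Genotypes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based detection of runs of homozygosity (ROH) in SNP-array
    genotypes, genomic inbreeding coefficients (F_ROH and excess-homozygosity
    F), population differentiation (pairwise and per-marker Fixation Index,
    principal components, method-of-moments identity-by-descent, genomic
    relationship matrix), ROH-island detection from within-population SNP
    occurrence profiles, and interval annotation of islands with genes and
    QTL. Includes readers and writers for PLINK text and binary dialects and
    VCF, a Balding-Nichols multi-population genotype simulator with planted
    autozygous tracts and full ground truth, and an end-to-end pipeline
    driver. Developed around the analysis of the three autochthonous Aosta
    cattle breeds (Valdostana Red Pied, Black Pied and Chestnut).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
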