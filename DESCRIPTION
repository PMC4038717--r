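Package: hbcgm
Title: Haplotype-Based Computational Genetic Mapping for Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Whole-genome haplotype-based computational genetic mapping
    (HBCGM) for panels of inbred mouse strains. Enumerates short haplotype
    blocks over a strain-by-SNP genotype panel, tests the strain partition
    induced by each distinct block against quantitative trait means with a
    one-way analysis of variance, and prioritizes candidate genes with two
    resampling-style scores: a strain-subset robustness score and a
    multi-trait integration score, both built on censored sums of -log10
    p-values. Includes behavioral-pharmacology phenotype indices
    (opioid-induced hyperalgesia fractions, percent maximal possible effect,
    variable-slope dose-response fits, tolerance ED50 shifts), Pearson
    trait-correlation tables with Benjamini-Hochberg adjustment, a synthetic
    strain-panel generator with an embedded causal haplotype block for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    optparse,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
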