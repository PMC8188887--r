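Package: strainmapqtl
Title: Ancestral Haplotype Maps, Linkage Meta-Analysis and Differential
    Expression for Inbred Strain Panels
Version: 0.1.0
Authors@R:
    person("Strainmap", "Maintainers", email = "maintainers@strainmapqtl.org",
           role = c("aut", "cre"))
Description: Reconstructs ancestral haplotype maps from homozygous
    genotype calls of inbred strain panels (strain distribution pattern
    enumeration, run-based segment detection, haplotype-class region
    tiling, pairwise inter-strain diversity), performs QTL genome scans
    in experimental crosses (hidden Markov model genotype posteriors on a
    pseudomarker grid, additive-dosage score test on quantile-normalized
    phenotypes) combined across crosses by inverse-variance fixed-effect
    meta-analysis with a Cochran Q heterogeneity screen, and classifies
    microarray differential expression into shared and non-shared
    categories with cis annotation against the haplotype map.  A
    synthetic-data module generates founder pools, inbred-strain founder
    mosaics, crosses with planted QTLs and cis-driven expression so that
    every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    optparse,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
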