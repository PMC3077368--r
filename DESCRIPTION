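Package: accelscreen
Title: Lineage-Accelerated Evolution Screens with Regional Rate Adjustment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Likelihood-ratio screens for lineage-specific rate acceleration
    in protein-coding genes (MG94xHKY85 codon model) and conserved noncoding
    elements (HKY85), with the expected rate on each branch calibrated from
    neighboring loci (regional synonymous rates and per-branch constraint
    scaling). Includes gene-wise Fisher combination of element p-values,
    Storey q-value false discovery rate control, candidate-set enrichment
    tests, allometric regression and squared-change parsimony ancestral
    reconstruction of life-history ratios, a candidate-gene case-control
    association stage (QC filters, allelic/genotypic chi-square, quantitative
    Wald tests, logistic covariate adjustment, simpleM effective-test
    correction), and a fully seeded synthetic-data generator for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
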