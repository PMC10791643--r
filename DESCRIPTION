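Package: edcscan
Title: Discovery and Comparative Analysis of Epidermal Differentiation
    Complex Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for locating and classifying genes of the epidermal
    differentiation complex (EDC) in genomic sequence: translated
    seed-and-extend homology search with the low-complexity filter
    disabled, splice-site-aware gene-model construction for
    single-coding-exon (SEDC), S100A and S100 fused-type protein (SFTP)
    genes, pseudogene flagging, amino-acid-composition hierarchical
    clustering of low-complexity proteins, neighbor-joining phylogenies
    of S100 domains with bootstrap support and outgroup rooting,
    orthology calling from reciprocal best hits, local synteny and
    phylogenetic grouping, and gene-order rearrangement reconstruction.
    A locus simulator with full ground truth makes every stage testable
    without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
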