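Package: famburden
Title: Gene-Family Burden, Clustering, Expression and Phenotype-Convergence
    Analysis for Neurodevelopmental Disorder Gene Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for gene-family approaches to
    neurodevelopmental-disorder (NDD) gene discovery. Ingests proband variant
    tables, classifies variants (LGD, severe missense by CADD tier), applies
    proband exclusion rules and a minimum-proband candidate-gene rule; clusters
    protein family members by pairwise global-alignment percent identity;
    tests per-gene excess of de novo variants against expected counts from
    pluggable per-gene mutation-rate models with exact Poisson tails and
    family-wise error correction; scores positional clustering of missense
    variants with an exact 1-D k-medoids statistic and permutation tests;
    computes single-cell cell-type expression enrichment, fold-change Z-scores
    and expression-profile correlations; builds proband-by-phenotype matrices
    with characteristic-phenotype filtering, pairwise Fisher tests and
    homology-phenotype concordance; intersects genes with genomic-disorder
    intervals; and generates fully synthetic inputs with known ground truth so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    methods,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    vegan,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
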