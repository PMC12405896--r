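Package: minegwas
Title: Adaptive GWAS Design and Ensemble Fitting of Genome-Wide Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for adaptive, staged genome-wide association studies in
    highly selfing crops. Single-nucleotide polymorphisms are collapsed into
    chromosomal bins of at least 50 kb (the "sum method") to form a normalized
    reference-allele dosage design matrix; genome-wide linear and mixed linear
    models are then fitted as Boltzmann ensembles with a customized Metropolis
    sampler featuring a dynamic stepwidth adjuster. The resulting parameter
    ensembles drive (i) selection of the maximally informative accession panel
    for the next season, by maximizing the determinant of the covariance or
    correlation matrix of ensemble trait predictions, and (ii) feature
    selection of trait-associated chromosomal regions via linear projection,
    Bayesian interval and Benjamini-Hochberg filters. A synthetic-data
    generator (genotypes with selfing-induced excess homozygosity, replicated
    field designs, simulated traits with known causal bins) makes every stage
    testable, and a gene finder intersects selected bins with a local GFF3
    annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    optparse,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm
Config/testthat/edition: 3
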