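Package: qtsmap
Title: Multi-Strategy Association Mapping of Quantitative Trait SNPs in
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping of quantitative trait SNPs (QTSs) in
    biparental recombinant-inbred-line (RIL) populations. Implements
    genotype quality control (missing-rate and 1:1 segregation filters,
    +/-1 parental coding), linkage-disequilibrium decay estimation,
    three SNP-set strategies (genome-wide, QTL-region and gene-based),
    an F-statistic candidate screen, a two-step mixed-linear-model scan
    (additive then covariate-conditioned epistasis) with permutation
    thresholds controlling the experiment-wise type I error, Gibbs-sampler
    estimation of genetic effects and variance components with per-QTS
    heritability partitioning, and breeding-value prediction of parental,
    best and superior genotypes. A single-seed-descent simulator generates
    RIL genotypes and multi-environment phenotypes with known ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
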