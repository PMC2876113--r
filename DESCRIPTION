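Package: tsetsepop
Title: Multi-Marker Population Structure Analysis for Tsetse Control Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic and morphometric toolkit for deciding between
    suppression and eradication of tsetse (Glossina) populations. Implements
    Weir-Cockerham and hierarchical F-statistics with permutation tests,
    null-allele and linkage-disequilibrium locus diagnostics,
    linkage-disequilibrium and heterozygote-excess effective population size
    estimators, heterozygosity-excess bottleneck tests under IAM/SMM/TPM
    mutation models, Cavalli-Sforza & Edwards chord distances with
    neighbour-joining trees, mitochondrial sequence diversity and Hudson
    differentiation statistics with a simplified parsimony network,
    generalized Procrustes wing morphometrics with partial warps and
    Mahalanobis discriminant analysis, and Mantel tests integrating the three
    marker systems. A hierarchical-F synthetic data generator emulates the
    five-site, two-region study design so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    ape,
    igraph,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
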