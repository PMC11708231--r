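Package: deltastats
Title: Five-Taxon Delta-Statistics for Admixture Direction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Site-pattern tests of admixture and its direction on five-leaf
    phylogenetic trees. Counts polarized biallelic allelic patterns under the
    outgroup mutation assumption, computes binomial and composed scaled
    Delta-statistics (with DFOIL and Partitioned D as special cases), their
    Z-scores, Wald intervals and sign classifications, matches observed
    signatures against encoded prediction tables for the symmetric,
    asymmetric and quasisymmetric tree shapes, runs windowed genome scans
    for local-ancestry classification, and validates every predicted
    signature with a built-in structured-coalescent simulator supporting
    unidirectional gene-flow edges, ghost populations and ancient samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
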