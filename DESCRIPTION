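Package: epigain
Title: Entropy-Based Genome-Wide Gene-Gene Interaction Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-gene interactions (epistasis) in case-control
    genotype data using an information-gain (mutual information) statistic
    whose null distribution is approximated analytically by a gamma
    distribution, so that genome-scale scans need no permutation testing.
    Provides an exhaustive scan over all k-SNP combinations, a stepwise
    forward-selection search for higher-order interactions, readers for
    PLINK binary and TSV genotype formats with standard quality-control
    filters, a penetrance-model case-control simulator, and a replicate
    experiment harness for type-I-error, power and search-efficiency
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
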