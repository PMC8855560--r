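Package: laswitch
Title: Liquid Association Screening for Switch Genes and Cross-Shaped
    Co-Expression Triplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-way gene interaction (liquid association) screening for
    bulk expression data. Selects candidate switch genes as genes that are
    both differentially expressed (empirical-Bayes moderated t with
    Benjamini-Hochberg control) and bimodally distributed (Hartigan dip
    test), screens all (X1, X2 | X3) triplets for cross-shaped
    co-expression with a tertile correlation-difference filter, a
    product-moment liquid association statistic and a bootstrap Wald test
    with top-K Bonferroni correction, and checks the biological relevance
    of significant triplets against an ARACNE-style mutual-information
    regulatory network and hypergeometric gene-set over-representation
    with kappa-score term grouping. Includes a synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
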