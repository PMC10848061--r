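Package: sdnet
Title: Structural Connectome Analysis of Vulnerability to Sleep Deprivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weighted white-matter network analysis for a two-group study of
    vulnerability to total sleep deprivation. Builds streamline-count
    connectomes from plain-text matrices, applies fiber-count thresholding and
    region-volume correction, computes weighted graph metrics (strength,
    global/local/nodal efficiency, characteristic path length, clustering,
    small-world coefficients normalised against degree-preserving rewired
    nulls), identifies the rich club from a group sign-test backbone and
    quantifies its weighted coefficient against matched random networks, runs
    the network-based statistic (max-component permutation test), and provides
    the group and behavioural statistics (pooled t, chi-square, rank-sum Z,
    Benjamini-Hochberg FDR, Spearman). A synthetic cohort generator with a
    planted rich-club group difference and linked psychomotor-vigilance lapse
    counts makes every stage testable without imaging data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
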