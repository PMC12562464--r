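Package: strclock
Title: Median-Joining Networks and Dual TMRCA Dating of Y-STR Haplotype Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening Y-chromosome gene pools for old, shared
    paternal lineages. Builds median-joining networks of Y-STR haplotypes
    partitioned by Y-SNP branch, resolves them into most-parsimonious trees,
    dates clusters with two independent molecular clocks (average squared
    distance to the founder and the rho statistic), applies a two-criterion
    screen for informative cross-population clusters, computes haplogroup
    frequency statistics with chi-squared homogeneity tests, and interpolates
    haplogroup frequency surfaces by inverse-distance weighting. Ships a
    stepwise-mutation-model simulator (star and coalescent genealogies,
    plus a full two-population regional scenario with known ground truth)
    for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    geosphere,
    ape
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
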