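Package: isodiff
Title: Differential Analysis of Stable Isotope-Resolved Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis of targeted stable isotope-resolved
    metabolomics (SIRM) data. Derives total metabolite abundances,
    isotopologue proportions (mass distribution vectors, MDVs) and
    fractional contributions (mean enrichment) from corrected isotopologue
    measurements; performs pairwise, multi-group and consecutive time-point
    differential testing with parametric, rank-based and permutation tests
    under Benjamini-Hochberg false discovery rate control; compares whole
    MDV labeling profiles by Spearman rank correlation; provides a PCA
    overview; and integrates metabolite results with differential gene
    expression through pathway-scoped metabolograms and network projection.
    Ships a deterministic synthetic-data generator emulating a glioblastoma
    13C6-glucose tracing design (two conditions in triplicate, and a six
    time-point labeling kinetics course), a YAML-configured pipeline and a
    command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
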