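Package: mvspop
Title: Metavariant Species Construction and Population Genomics from
    Reference-Free Metagenomic Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters reference-free metagenomic variants (metavariants)
    into species-level units called metavariant species (MVS) without any
    reference genome. Candidate clusters are produced by density-based
    clustering of the per-sample depth-of-coverage matrix over a grid of
    (epsilon, minPts) parameters, scored by the negative-binomial fit of
    their coverage distributions and by their size, and a greedy
    maximum-weighted independent set rule selects non-overlapping clusters.
    Selected clusters are filtered on coverage expectations and used to
    compute population-genomic statistics: allele frequencies, per-locus
    F_ST, the Lewontin-Krakauer statistic with chi-square outlier tests,
    and between-sample pairwise F_ST matrices. Includes a synthetic
    community generator, clustering evaluation metrics (recall, precision,
    signal-to-noise, purity, entropy), a toy VCF writer/parser, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
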