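Package: seednet
Title: Seed-Gene Protein Interaction Subnetworks, Connectivity Nulls and
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein-protein interaction subnetworks seeded by one or
    two gene sets: candidate genes recruit their direct interactors and all
    shortest paths to their nearest candidate (or closest target) genes in
    the full interactome.  Reports connectivity statistics (minimum and
    average shortest path length with a sentinel distance for disconnected
    pairs, disconnected-candidate counts) against randomized gene-set
    baselines, and Fisher exact over-representation of pathway, disease,
    drug and GWAS annotation catalogs among subnetwork genes.  Reads
    tab-separated interactome edge lists, three-namespace gene identifier
    tables and GMT annotation catalogs; writes SIF networks, plain-text gene
    lists and a self-contained JSON results document.  Includes a synthetic
    fixture generator so the full pipeline runs without any database
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
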