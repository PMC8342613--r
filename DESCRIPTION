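Package: taxathresh
Title: Similarity-Threshold Calibration for Higher-Taxon Assignment from
    DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating DNA-barcode-based assignment of species
    proxies (Barcode Index Numbers, BINs) to higher taxonomic ranks such as
    order and family. Implements uncorrected p-distances with pairwise
    deletion and per-pair overlap counts, single-linkage divergence
    clustering with silhouette-based representative selection for library
    dilution, a modified leave-one-out nearest-neighbour identifier with
    divergence-exclusion rules, ROC/Youden and precision-based (P100, P99,
    P95) similarity-threshold selection, intra- and inter-taxon divergence
    and barcode-gap summaries with divergence-versus-richness regression,
    and a seeded hierarchical barcode-library simulator so that every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ape,
    cluster,
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
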