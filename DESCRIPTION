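Package: osteoatlas
Title: Network Propagation, Panel Imputation and Tissue-Axis Annotation for
    Skeletal Single-Cell and Spatial Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A composable toolkit for linking polygenic disease signals to
    cell states and space in developmental skeletal atlases. Implements
    random-walk-with-restart propagation of linkage-disequilibrium-weighted
    GWAS scores over enhancer-driven gene-regulatory networks with
    permutation z-scores and enriched-subnetwork extraction; k-nearest
    neighbour imputation of unmeasured genes and transfer of cell labels
    from a droplet reference onto targeted in situ sequencing cells via a
    shared normalized gene panel; and hexagonal-grid migration of raster
    tissue annotations with structure-distance features and a continuous
    tissue maturation axis mapped onto spatial transcriptomics spots.
    Ships deterministic synthetic-data generators for every input class so
    the full pipeline runs end to end without external downloads.
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
    Matrix,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
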