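Package: phagetax
Title: Genome-Based Taxonomy of Bacteriophage Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-based classification of bacteriophage
    populations: reciprocal intergenomic nucleotide similarity (VIRIDIC-style
    seed-and-extend local alignment with high-scoring-pair merging),
    orthologous protein grouping (phams) by identity/coverage thresholds,
    two-tier cluster (subfamily) and sub-cluster (genus) assignment,
    core/accessory/unique pangenome partitioning, gene presence/absence
    distance matrices with NEXUS export for splits networks, and a synthetic
    phage-population generator with planted taxonomy for end-to-end
    validation. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    IRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
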