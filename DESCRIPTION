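Package: carotscan
Title: Homolog Curation, Tree-Guided Dereplication, and Horizontal
    Gene Transfer Scanning for Carotenogenesis Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a protein-family curation and
    phylogenetics workflow for detecting horizontally transferred carotenoid
    biosynthesis domain cassettes in heterotrophic eukaryotes. Provides
    length-outlier filtering around the median, split-fragment merging,
    gap-column trimming of alignments, p/Poisson pairwise distances,
    neighbor-joining tree inference, midpoint rooting, nonparametric
    column-resampling bootstrap support, tree-guided taxonomic dereplication
    of sister tips by bit score, N-to-C domain-architecture resolution and
    fusion-pattern classification, a scan for taxonomically disjunct
    eukaryote clades nested in prokaryotic context, Beer-Lambert conversion
    of absorbance spectra to beta-carotene mass, and a synthetic-data
    generator with ground truth that emulates vertical domain evolution plus
    horizontal transfer of a multi-domain cassette.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
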