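Package: paleokaryo
Title: Comparative Paleogenomics of Plant and Animal Karyotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified comparative-paleogenomics toolkit for plant and animal
    genomes. Filters pairwise CDS alignments with cumulative identity (CIP)
    and cumulative aligned-length (CALP) criteria to call ortholog and
    paralog pairs, chains them into statistically validated synteny and
    duplication blocks, merges blocks across genomes into contiguous
    ancestral regions (CARs) and ancestral karyotypes, replays and infers
    parsimonious whole-genome-duplication / fission / fusion scenarios on
    colored karyotypes, and profiles gene and transposable-element
    landscapes in fixed-size windows. Ships a genome-evolution simulator
    (protochromosome ancestor, scripted rearrangements, post-duplication
    gene loss, divergence-dependent identity decay, plant- or animal-like
    repeat spatial structure) so every stage is testable end to end.
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
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
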