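Package: oligotag
Title: High-Throughput DNA Barcoding of Tagged Oligochaete Specimens for
    Sediment Quality Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for abundance-based sediment bioassessment from
    high-throughput DNA barcoding of individually tagged aquatic oligochaete
    specimens. Covers quality filtering and exact dual-tag demultiplexing of
    paired-end COI amplicon reads, quality-aware pair merging, per-specimen
    dereplication, chimera removal and 97 percent OTU clustering, Kimura
    two-parameter distance-threshold lineage assignment against a local COI
    reference database with per-genus threshold overrides, neighbour-joining
    placement of new lineages, the IOBS stream index and the lake
    percentage-of-sensitive-taxa metric with their quality classes, and the
    morphology-versus-genetics concordance analysis (log-linearized
    regressions and class-agreement tables). A synthetic-data module generates
    reference databases, site communities along a pollution gradient, tagged
    paired-end reads with substitution errors and chimeras, and a coarsened
    morphological observer, all with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
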