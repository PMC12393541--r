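Package: tandemor
Title: Quantifying Monogenic Odorant Receptor Expression in Tandem Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantification pipeline for studying how olfactory sensory
    neurons achieve monogenic odorant receptor (OR) expression from tandem
    gene arrays. Implements tandem-array detection and filtered gene-pair
    sampling from genome annotations, stranded relative-coverage statistics
    for transcriptional readthrough and antisense transcription, promoter
    bidirectionality scoring from capped-small-RNA start sites, single-cell
    chosen-OR assignment with staircase coexpression and lncRNA correlation
    analysis, and a full RNA-FISH confocal-stack quantification pipeline
    (depth correction, signal segmentation, nuclear/cytoplasmic ROI
    measurement, robust normalization and cell classification). Seeded
    synthetic-data generators with ground truth make every stage testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    rlang,
    withr,
    Matrix,
    jsonlite,
    yaml,
    igraph,
    EBImage,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
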