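Package: rnaforge
Title: Generative RNA Language Models and Thermostable Mutation Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building compact generative models of structured RNA
    families and mining them for stabilizing mutations. Provides overlapping
    n-gram tokenization of RNA, a small decoder-only autoregressive language
    model with per-layer rotary position encoding and RMS normalization, a
    structure-conditioned autoregressive model over k-nearest-neighbor contact
    graphs, alignment quality-control filters (ambiguity, consensus coverage,
    length and non-canonical base-pair outliers), identity-based train/test
    splitting, minimum-atom-distance matrices and contact maps from PDB/mmCIF
    coordinates, and the finetuned-versus-pretrained mutation scan: per-column
    Jensen-Shannon divergence with seed/occupancy masking, top-N overlap
    matrices, and delta-delta-log-probability scoring of candidate mutations
    against a single-mutant reference distribution. Includes a synthetic RNA
    family simulator with planted thermophile compositional shifts that serves
    as ground truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    matrixStats,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
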