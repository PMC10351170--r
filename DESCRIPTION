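Package: alignsafe
Title: Alignment-Safe Intervals from Suboptimal Protein Alignment Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers alignment-safe sequence windows for pairs of protein
    sequences: maximal intervals contained in at least a proportion alpha
    of all global alignments whose score is within Delta of the optimum,
    computed by exact arbitrary-precision path counting on the affine-gap
    alignment graph. Provides cluster-level workflows (each member aligned
    against a representative), projection of windows onto both sequences,
    structure-retention benchmarking against per-residue secondary
    structure labels, exhaustive-enumeration oracles for verification, and
    a seeded synthetic cluster generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
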