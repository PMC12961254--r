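Package: smrnaploid
Title: Annotation-Free Small-RNA Targeting Analysis for Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based discovery of small-RNA (20-24 nt) target regions
    from alignment tables, fractional multi-mapper counting, TMM-normalized
    negative-binomial differential-targeting tests with Benjamini-Hochberg
    correction, and classification of polyploid-versus-parent genomic
    interactions (additive, dominant, transgressive). Includes hypergeometric
    tests for target-region sharing between sibling polyploids, per-length
    and feature-context summaries, MDS ordination of samples, and a
    seed-deterministic synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    stats,
    tools,
    utils,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
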