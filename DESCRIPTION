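Package: isocat
Title: Long-Read Splice-Variant Cataloging and Functional Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds splice-variant catalogs from noisy long-read alignments of
    a targeted multi-exon gene amplicon and prioritizes variants by coding
    potential, expression and conservation. Corrects read splice junctions
    against short-read junction support, collapses reads into transcript
    models by transcription start site and junction chain, filters by read
    support and quantifies by read reassignment. Predicts open reading
    frames, calls channel-forming potential from conserved-domain hits,
    ranks variants by expression ratio and TPM, detects cassette-exon
    events, aggregates per-exon conservation, builds triplet-exon homology
    queries and filters BLAST tabular hits, scores donor and acceptor splice
    sites with loadable maximum-entropy model tables, and renders aligned
    isoform-structure diagrams. Ships a synthetic-data generator with known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
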