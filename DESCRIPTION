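Package: orfmiss
Title: Discovery of Missing Genes and Absent Annotations in Prokaryotic
    Replicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects conserved but unannotated intergenic open reading
    frames ("missing genes") and unannotated copies of known genes
    ("absent annotations") in prokaryotic replicons. Enumerates maximal
    ORFs on both strands, partitions them by genomic context against the
    existing annotation, screens all-vs-all protein alignments by
    e-value and dual coverage, applies a two-stage taxonomy-aware
    classification with single-linkage family clustering, and scores
    every call with an alignment-uniqueness statistic (alpha). Also
    provides GC3, MUM-index genome distance, flank ultra-conservation
    checks, and a seeded synthetic pan-genome generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    igraph,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
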