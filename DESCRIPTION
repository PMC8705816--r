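Package: bifidophage
Title: Prophage and CRISPR Immunity Analysis for Bifidobacterium Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale comparative genomics of prophages and CRISPR-mediated
    phage immunity in human-associated Bifidobacterium. The package detects
    candidate prophage regions on annotated genomes, refines their boundaries
    using integrase/tRNA context and co-transcription criteria, classifies
    completeness, clusters regions by fragment-based average nucleotide
    identity, builds protein gene families with a from-scratch Markov
    clustering implementation, detects CRISPR repeat-spacer arrays, maps
    non-redundant spacers back onto prophages as protospacers, and computes
    intergenomic Genome-BLAST distances with neighbor-joining trees. A
    deterministic genome simulator implants prophages and CRISPR arrays with
    full ground truth so every stage can be validated without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    phangorn,
    igraph,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
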