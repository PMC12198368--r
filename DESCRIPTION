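Package: mitopunct
Title: Classification and Junction Accounting of Long-Read Mitochondrial Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing mitochondrial transcript processing from
    aligned long direct-RNA reads. Reads are classified as processed or
    unprocessed against an annotated polycistronic genome using a boundary
    tolerance rule, unprocessed reads are grouped by the gene junctions they
    span, and per-junction statistics (unprocessed fractions, pooled
    compositions, knockout-versus-control delta values, tRNA read-through
    fractions and 5' start-site tables) are computed. A synthetic read
    generator with per-junction cleavage probabilities, transcript turnover
    weights, poly(A)-capture bias and nanopore 5'-end truncation provides
    ground-truth fixtures for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
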