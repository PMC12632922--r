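Package: moveindex
Title: Move-Structure Full-Text Indexing of Pangenomes with Pseudo Matching
    Length Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds run-length Burrows-Wheeler transform (RLBWT) indexes for
    DNA pangenomes using the move structure: a single table supporting
    LF-mapping in constant-ish time with high locality of reference. Implements
    matching-statistics thresholds, run splitting that makes every threshold
    trivial (one bit per symbol), length-capped splitting for narrow bit
    fields, and two compressed representations of the destination-row id
    column (blocked delta encoding against a checkpoint table, and a sampled
    scheme that reconstructs ids by scanning). Supports Pseudo Matching Length
    (PML) queries for read classification, bit-exact index serialization, a
    command-line interface, and deterministic synthetic pangenome/read
    generators. Every component is validated against brute-force BWT oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
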