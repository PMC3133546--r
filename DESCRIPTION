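Package: refscaf
Title: Reference-Guided Scaffolding and Gap-Closure Primer Design for
    Bacterial Draft Genomes
Version: 0.1.0
Authors@R:
    person("Anna", "Kovacs", email = "anna.kovacs@example.org",
           role = c("aut", "cre"))
Description: Maps draft bacterial contigs onto one or more closed reference
    replicons with a native seed-and-chain aligner, assigns each contig to at
    most one replicon (multipartite genomes), orders and orients the mapped
    contigs into an N-gapped pseudocontig per replicon (splitting contigs that
    span the origin of a circular molecule), designs uniqueness-verified PCR
    primer pairs across the remaining gaps, and scans excluded contigs for
    reference proteins from unaligned regions via six-frame translation.
    Emits Artemis Comparison Tool (ACT) compatible crunch and EMBL feature
    table files for structural inspection, plus a synthetic genome/fragment
    generator with recorded ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
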