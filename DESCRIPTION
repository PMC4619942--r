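Package: spacedseeds
Title: Spaced-Seed Data Structures for de Bruijn Graph Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data structures and algorithms for de Bruijn graph assembly with
    spaced seeds: pairs of k-mers separated by a fixed gap. Provides a 2-bit
    DNA codec with bitwise-NOT complementation, a strand-folded four-hash
    Bloom filter for spaced-seed membership, a two-stage (cascading) counting
    Bloom filter backed by an 8-bit minifloat (1.4.3.-2) counter with
    unbiased probabilistic increments, an ABySS-style spaced-seed hash-table
    record with memory accounting, hit-pattern read error correction, a toy
    dual-wavefront assembler with blunt/branch tracking and branch trimming,
    genome uniqueness profiling as a function of the gap length, and a
    deterministic simulator for genomes, reads and count fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
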