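Package: superwalk
Title: Gadget Reductions and Exact Solvers for De Bruijn Superwalks with
    Multiplicities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructive machinery around the hardness of genome assembly
    under the de Bruijn superwalk model with exact edge multiplicities (DBSM).
    Provides the balanced non-overlapping character gadgets that encode binary
    strings, the polynomial reductions from Shortest Common Superstring (SCS)
    through Common Superstring with Multiplicities (CSM) to DBSM, witness
    mappings in both directions, exact exhaustive solvers for all three
    decision problems at desk scale, the polynomial Eulerian special case for
    single-edge reads, seeded instance generators, and a command-line
    interface over a small JSON instance dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    Biostrings,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
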