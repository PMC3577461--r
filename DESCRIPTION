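Package: cmfinder
Title: Entropy-Based Detection of Compensatory Mutations in Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects coevolving (compensatory) residue-site pairs and sites in
    protein multiple sequence alignments. Combines a normalized
    mutual-information coupling score with a variant that upscales
    BLOSUM62-dissimilar compensatory exchanges via a trained 400x400 doubly
    stochastic matrix over amino-acid pair states, and calls significant pairs
    and sites under an alignment-specific beta null with false-discovery-rate
    control. Includes alignment pre-processing filters, Sinkhorn training of
    the pair-transition matrix from an alignment corpus, and a seeded
    synthetic-alignment generator with planted coevolving column pairs for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
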