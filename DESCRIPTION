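Package: p3dnbr
Title: Gaussian Shape and Pharmacophore Similarity Search for 3-D Conformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional similarity search over multi-conformer small-molecule
    sets using atom-centered Gaussian shape overlap (shape Tanimoto) and fictitious
    pharmacophore feature atoms (color Tanimoto). Provides diverse-conformer
    ordering of ensembles, tiered reference-shape fingerprints with alignment
    recycling, a staged volume/fingerprint-filtered neighbor search, and a compact
    64-bit codec for rigid superpositions (8-bit quaternion components plus a
    log-scale translation encoding). Includes SDF input/output, a compact binary
    conformer-set format with quantized coordinates, and a deterministic synthetic
    conformer generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ChemmineR,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
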