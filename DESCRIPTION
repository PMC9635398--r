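Package: FvDesign
Title: Structure-Conditioned Design of Antibody Fv Subsequences by
    Gradient-Based Hallucination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gradient-based design ("hallucination") of antibody Fv
    subsequences -- CDR loops and the VH-VL interface -- conditioned on a
    target backbone structure through a differentiable sequence-to-geometry
    oracle. Provides binned inter-residue geometry targets (CA, CB and N-O
    distances and the theta/phi/omega orientation channels), a categorical
    cross-entropy geometric loss restricted to 10 Angstrom CA contacts,
    sequence and motif (KL) losses, wildtype seeding, reduced-alphabet
    sampling, a normalized-SGD design loop, library evaluation metrics
    (amino-acid recovery, PSSMs, Bhattacharyya overlap, perplexity,
    Levenshtein profiles, FR scores), sequence-level developability metrics
    (instability index, GRAVY, net charge), and a fold/bind screening
    pipeline with pluggable adapters plus offline mock adapters. A bundled
    deterministic toy oracle with a known optimum makes the whole pipeline
    testable end-to-end without external structure-prediction models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
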