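Package: novanorms
Title: AI-Enhanced Semantic Feature Norms: Verification Cascades, Signal
    Detection Evaluation, and Triadic Similarity Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and evaluating AI-enhanced semantic feature
    norms. Represents concept-by-feature norm data as binary matrices with
    per-cell provenance (elicited, imputed, absent), collapses near-duplicate
    feature phrasings by complete-linkage clustering of phrase embeddings,
    fills in unlisted concept-feature pairs through a two-stage verifier
    cascade (a primary verifier whose positive verdicts are re-checked by a
    secondary verifier, retained only on agreement), and scores verification
    strategies against unanimous human judgments with signal-detection
    d-prime and bootstrap confidence intervals. Also constructs maximally
    disagreeing triadic similarity triplets between two semantic spaces via
    Procrustes alignment of cosine dissimilarity matrices, predicts triadic
    choices, and scores agreement with (real or simulated) human majority
    votes. Includes a fully seeded synthetic-data module so every pipeline
    stage can be exercised without external data or model access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
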