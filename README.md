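# novanorms

Tools for building and evaluating **AI-enhanced semantic feature norms**:
binary concept-by-feature matrices in which sparse human-elicited data are
enriched by machine verifiers whose verdicts are validated against reliable
human judgments.

Feature norms represent a concept as a binary vector over nameable
properties ("has legs", "has a long neck"). Free listing captures only a
fraction of what people know — most raters verify *has a long neck* as true
of a beer bottle, but nobody lists it — and exhaustively verifying every
concept-feature pair by hand is quadratic in the inventory. The workflow
this package implements:

1. collapse near-duplicate feature phrasings by complete-linkage clustering
   of phrase embeddings (`cluster_features()`, `merge_features()`);
2. fill in the unlisted cells with a **two-stage verifier cascade**: a
   primary verifier answers every pair, a secondary verifier re-checks its
   positives, and a 1 is retained only when both agree
   (`cascade_verify()`, `impute_matrix()`). Under independent errors the
   cascade's hit rate is *h₁h₂* and its false-alarm rate *f₁f₂* — a small
   hit cost for a multiplicative collapse in false alarms;
3. validate any verification strategy against unanimous human judgments by
   signal detection (`build_gold_set()`, `dprime()`, `bootstrap_ci()`,
   `compare_strategies()`), with **d′ = z(H) − z(F)** and half-count
   clamping of perfect rates;
4. compare two semantic spaces behaviorally with **maximally disagreeing
   triadic triplets** — (target, A, B) items where space 1 puts the target
   closer to B and space 2 closer to A (`procrustes_align()`,
   `generate_divergent_triplets()`, `predict_choices()`,
   `score_agreement()`);
5. simulate every input — block-structured latent truth matrices, sparse
   elicitation, noisy verifiers with configurable hit/false-alarm rates,
   logistic triadic raters — fully seeded (`sim_config()` and the
   `simulate_*()` family), so the whole pipeline runs with no external data
   or model access.

All cells carry provenance (`elicited` / `imputed` / `absent`), the on-disk
formats are plain text (long TSV for matrices, JSONL for verdicts,
judgments and choices, TSV for gold sets and triplets), and every seeded
stage is byte-reproducible.

## A worked example

```r
library(novanorms)

cfg   <- sim_config(seed = 42)            # 60 concepts x 400 features, 6 blocks
truth <- simulate_truth_matrix(cfg)       # latent "complete knowledge"
human <- simulate_elicitation(truth, cfg$p_list, seed = 43)  # sparse listing

density_stats(truth)
#> density: 33.63 features/concept, 5.04 concepts/feature, singleton fraction 0.015, 2018 ones
density_stats(human)
#> density: 0.83 features/concept, 0.12 concepts/feature, singleton fraction 0.980, 50 ones

primary   <- make_simulated_verifier(truth, hit = 0.95, fa = 0.05, seed = 101)
secondary <- make_simulated_verifier(truth, hit = 0.95, fa = 0.05, seed = 202)
nova <- impute_matrix(human, primary, secondary)
density_stats(nova)
#> density: 31.68 features/concept, 4.75 concepts/feature, singleton fraction 0.028, 1901 ones
```

The elicited matrix has under one feature per concept and is 98% singleton
features; cascade imputation recovers the latent density (31.7 of 33.6
features per concept) while singleton dominance collapses to 3% — the
sparse-to-dense contrast that motivates AI enhancement. Scoring the primary
verifier against a 1,000-pair unanimous gold set:

```r
gold <- build_gold_set(simulate_gold_judgments(truth, 1000, seed = 7))
vt   <- verify_pairs(gold[, c("concept", "feature")], primary)
dprime(confusion_counts(gold, vt))
#> d' = 3.3925 (H = 0.9580, F = 0.0480)
```

as expected for a verifier operating at hit .95 / false-alarm .05
(z(.95) − z(.05) ≈ 3.29). A command-line wrapper for the same pipeline
(`simulate`, `reduce`, `verify`, `impute`, `evaluate`, `triplets`, `agree`)
ships at `inst/cli/nova`; run it with `--help` for flags. Each run writes a
JSON manifest next to its outputs.

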