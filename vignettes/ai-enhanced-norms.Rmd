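---
title: "AI-enhanced semantic feature norms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AI-enhanced semantic feature norms: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novanorms)
```

## The problem

Semantic feature norms represent concepts ("alligator", "accordion") as
binary vectors over human-attributed properties ("has legs", "has keys").
Free listing elicits only a small fraction of what people actually know: most
participants list *has a long neck* for a giraffe but not for a beer bottle,
yet readily verify it as true of both when asked. Exhaustive human
verification of every concept-feature pair is quadratic in the inventory and
infeasible at scale, which is where machine verifiers (in practice, large
language models) come in — provided their verdicts are validated against
reliable human judgments rather than trusted blindly.

This package implements that workflow end to end:

1. **norm matrices** — binary concept-by-feature matrices where every cell
   carries a provenance: `elicited` (a participant produced it), `imputed`
   (a verifier cascade confirmed it), or `absent`;
2. **feature reduction** — collapsing near-identical phrasings (*is furry*,
   *feels furry*) by clustering phrase embeddings;
3. **verification** — a fixed prompt template, a deterministic response
   parser, and a two-stage *reverification cascade*;
4. **signal-detection evaluation** — scoring any verification strategy
   against unanimous human judgments with d′ and bootstrap intervals;
5. **triadic benchmarking** — constructing triplets on which two semantic
   spaces disagree about similarity, and scoring which space better predicts
   (real or simulated) human majority votes;
6. **synthetic simulation** — a fully seeded generator for every input the
   pipeline needs, so everything above is testable with no external data or
   model access.

## The verification model

A verifier is any function from prompt text to raw response text. The prompt
is fixed:

```
In one word True or False, answer the following question:
Is the property [x] true for [y]? Answer:
```

with the feature `x` and concept `y` substituted and the square brackets
kept. Two-shot prompting prepends two exemplar blocks in the identical
template — one true, one false, true first, the same pair for every prompt.
The shipped default exemplars are ("dog", "has ears") → True and
("alligator", "has wheels") → False; they are configuration, not a claim
about optimal in-context examples.

Raw responses are truncated to five whitespace tokens and scanned left to
right; the first decisive token wins. A token containing `true` or `yes`
(case-insensitive substring) is positive; a token containing `false`, or
equal to `no` after stripping surrounding punctuation (or `no` followed by a
non-letter, as in `no-brainer`), is negative. Bare `no` is deliberately
*not* matched as a substring — otherwise "nothing" and "known" would read as
denials. Anything undecided defaults to negative, so the parser is total.

### The reverification cascade

`cascade_verify()` queries a primary verifier for every pair and re-checks
only its positive verdicts with a secondary verifier; the final decision is
the logical AND. Under independent error rates the cascade's hit rate is
`h1*h2` and its false-alarm rate `f1*f2`: a small sacrifice in hits buys a
multiplicative collapse of false alarms, which is what lets a cheap, leaky
primary model be combined with a stricter secondary one. `impute_matrix()`
routes every zero cell of an elicited matrix through the cascade; ones are
never queried and never flipped, and every new 1 is provenance-`imputed`.

## Signal-detection evaluation

Verification strategies are scored against a *gold set*: concept-feature
pairs on which at least `min_raters` (default 5) non-skip human judgments
were unanimous. Treating gold labels as signal and verifier decisions as
guesses gives hit and false-alarm rates, and

d′ = z(H) − z(F),

with z the inverse standard-normal CDF. Perfect rates are clamped into
[1/(2N), 1 − 1/(2N)] per class (the half-count convention) so z stays
finite; N is each rate's own denominator. Confidence intervals are
percentile bootstrap over gold *pairs* (the unit of analysis), with one
refinement: inside bootstrap replicates the clamp bounds are computed from
the full gold set's class sizes rather than each replicate's. This treats
the clamp as a fixed smoothing constant of the dataset; without it, a gold
set on which the verifier is perfect in both classes would show spurious
interval width coming purely from the clamp bound resampling.
Replicates that lose an entire class are recorded as missing; more than 10%
missing aborts with an instability error rather than returning a shaky
interval.

## The triadic benchmark

Two semantic spaces are compared behaviorally. Both are cosine
dissimilarity matrices over the same concepts (concepts with all-zero
feature vectors are dropped — cosine is undefined for them). The matrices
are Procrustes-aligned — each configuration centered and scaled to unit sum
of squares, then one rotated onto the other by the SVD closed form,
reflections allowed by default — and the per-concept squared residuals rank
which concepts the two spaces disagree about most.

Divergent triplets (target, option A, option B) are chosen so that space 1
puts the target strictly closer to B while space 2 puts it strictly closer
to A. Each candidate is scored by the *smaller* of its two divergence
margins, so near-ties in either space score low; the top `per_target_quota`
candidates are kept per target, with an optional global cap by score. A
strictness margin of 1e-12 on both inequalities keeps floating-point ties
from fabricating triplets. Left/right presentation is randomized by seed,
with the divergence orientation recorded.

Agreement is scored against the per-triplet majority vote of the raters
(vote ties excluded and counted): the fraction of voted triplets where each
space's nearest-option prediction matches the majority, an exact two-sided
binomial test of that fraction against chance, and a paired t-test on the
per-triplet agreement indicators of the two spaces (df = n − 1). When the
indicators separate perfectly the t statistic diverges; it is reported as
`Inf` with p = 0 rather than NA, reserving NA for the uninformative
all-zero-differences case.

## The synthetic-data generator

`sim_config()` defines the reference synthetic study, emulating the shape of
real norming data without claiming linguistic realism:

| parameter | default | meaning |
|---|---|---|
| `n_concepts` × `n_features` | 60 × 400 | matrix size |
| `n_categories` | 6 | taxonomic blocks (near-even assignment) |
| `p_within` / `p_across` | 0.40 / 0.02 | P(true) for block-matching / crossing pairs |
| `p_list` | 1/35 | per-true-feature elicitation probability |
| `verifier_hit` / `verifier_fa` | 0.95 / 0.05 | simulated verifier operating point (d′ ≈ 3.3) |
| `choice_noise` | 0.3 | logistic scale on distance differences for triadic raters |

The block-Bernoulli truth matrix gives each concept about 33 true features
with category structure. `p_list = 1/35` reproduces the roughly 35-fold
density gap between spontaneously listed features and verifiable knowledge
(tens of features per concept versus hundreds in real norms), which is the
regime in which imputation matters. The verifier operating point mirrors a
verification strategy that discriminates well (d′ > 3), and `choice_noise`
is calibrated so that majority votes of ~31 simulated raters agree with the
generating space on roughly 85–90% of trials — the agreement level human
triadic studies report — rather than behaving as error-free distance oracles.

Simulated verifier randomness is keyed by a hash of (seed, concept,
feature), so a verdict does not depend on query order or on which subset of
pairs the cascade happens to ask about, and distinct seeds give independent
verifiers. Simulated raters draw each choice with
P(pick A) = logistic((d(t,B) − d(t,A)) / `choice_noise`).

What the generator does *not* emulate: correlated verifier errors across
related pairs (real LLMs fail systematically, not independently), rater
individual differences, polysemy, and any actual lexical content of
features. Passing tests therefore demonstrate that the machinery is correct
under its stated statistical model, not that any particular LLM is a good
verifier for real norms.

## Scales used in the checks

The test suite and `scripts/acceptance.R` run four synthetic experiments,
sized so the statistics are sharp at desk scale: signal-detection parameter
recovery on 6,000-pair gold sets (the interval should cover
z(.95) − z(.05) ≈ 3.29); cascade rates measured over 50,000 pairs against
the analytic (0.855, 0.015) operating point; the density contrast on the
default 60 × 400 study; and the triadic benchmark on a denser
60 × 2400 truth (`p_within` 0.5, `p_across` 0.03, same 1/35 elicitation).
The denser configuration exists because the triadic experiment needs an
elicited space with realistic *absolute* density: at under one elicited
feature per concept, concepts rarely share features, nearly all elicited
distances tie, and divergent triplets barely exist — a degeneracy of the
toy scale, not of the method.

## Numerical choices and edge cases

- Identifiers are case-folded, trimmed labels; two distinct labels that
  collide after folding are an error, so joins across files are
  deterministic.
- Feature clustering is complete-linkage agglomeration under cosine
  similarity: two phrases share a cluster only if *every* within-cluster
  pair clears the threshold (default 0.95, conservative enough to keep
  close synonyms like *is hairy* / *is furry* apart). A 1e-12 tolerance on
  the cut height lets threshold 1.0 still merge exactly-collinear vectors
  despite floating-point dust. Zero-norm embedding vectors are an error
  naming the phrase.
- Cluster representatives are the most elicitation-frequent member phrase,
  ties and the no-counts case resolved lexicographically.
- The long-TSV writer emits every cell, ordered by concept id then feature
  id. This makes files larger than a sparse listing but guarantees that
  matrix *shape* — including concepts and features with no true cells —
  survives a round trip through a format whose header carries no metadata,
  and that identical matrices produce byte-identical files.
- `dense-csv` is an interchange convenience and loses provenance: all 1s
  read back as `elicited`.
- Procrustes alignment requires at least 3 concepts and errors on
  zero-variance configurations and label mismatches; reflection can be
  disallowed, in which case the smallest singular direction is flipped.
- Verifier exceptions mark a pair failed (decision FALSE) and the run
  continues; failure counts ride along in the verdict-table attributes and
  the CLI run manifest.

## Known limitations

- No real LLM backends ship with the package; the verifier contract (prompt
  in, text out) is where an HTTP adapter would plug in, and everything
  downstream is backend-agnostic.
- Verifier error independence is assumed by the cascade analysis; correlated
  errors would make the cascade's false-alarm reduction less than
  multiplicative.
- Dense in-memory storage is comfortable to a few thousand concepts and
  features; norm inventories far beyond that would want a sparse backend.
- The feature-reduction step clusters whatever embeddings it is given; with
  the toy hashing embedder, "similarity" means shared character trigrams,
  which is sufficient for exercising the algorithm but not for real phrase
  semantics.
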