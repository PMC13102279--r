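# Independent oracles used to freeze or cross-check expected values. These
# deliberately avoid the code paths they validate.

# Inverse standard-normal CDF by numerical root-finding on pnorm.
qnorm_oracle <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(x) stats::pnorm(x) - pp,
      interval = c(-12, 12), tol = 1e-13
    )$root
  }, numeric(1L))
}

# Exact two-sided binomial p-value versus 0.5 by direct tail summation.
binom_p_oracle <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-7)])
}

# Brute-force divergent-triplet enumeration over all ordered (t, a, b):
# keeps triples where space 1 has the target strictly closer to b and
# space 2 strictly closer to a. Independent of generate_divergent_triplets.
brute_force_triplets <- function(d1, d2, min_margin = 1e-12) {
  labels <- rownames(d1)
  n <- length(labels)
  rows <- list()
  for (t in seq_len(n)) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b || a == t || b == t) next
        m1 <- d1[t, a] - d1[t, b]
        m2 <- d2[t, b] - d2[t, a]
        if (m1 > min_margin && m2 > min_margin) {
          rows[[length(rows) + 1L]] <- data.frame(
            target = labels[t], option_a = labels[a], option_b = labels[b],
            score = min(m1, m2), stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      target = character(), option_a = character(),
      option_b = character(), score = numeric()
    ))
  }
  do.call(rbind, rows)
}

# All set partitions of 1..n (n small), for the exhaustive clustering oracle.
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Partitions where every within-block pair has cosine similarity >= thr.
valid_partitions <- function(S, thr) {
  Filter(function(p) {
    all(vapply(p, function(block) {
      if (length(block) < 2L) return(TRUE)
      pairs <- utils::combn(block, 2L)
      all(S[cbind(pairs[1L, ], pairs[2L, ])] >= thr - 1e-12)
    }, logical(1L)))
  }, all_partitions(nrow(S)))
}

# Random symmetric dissimilarity matrix with zero diagonal (continuous
# entries, so strict inequalities hold almost surely).
random_dissimilarity <- function(n, labels = sprintf("w%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  vals <- stats::runif(n * (n - 1) / 2, 0.05, 1.95)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Canonical comparable form of a cluster assignment: partition of phrases as
# a sorted list of sorted blocks.
partition_signature <- function(blocks) {
  blocks <- lapply(blocks, sort)
  paste(sort(vapply(blocks, paste, character(1L), collapse = ",")), collapse = "|")
}

# Small norm matrix builder for fixtures.
nm_fixture <- function(concepts, features, ones, provenance = "elicited") {
  cells <- NULL
  if (length(ones)) {
    cells <- data.frame(
      concept = vapply(ones, `[[`, character(1L), 1L),
      feature = vapply(ones, `[[`, character(1L), 2L),
      value = 1L,
      provenance = provenance,
      stringsAsFactors = FALSE
    )
  }
  norm_matrix(concepts, features, cells)
}

# Verifier that answers from a fixed lookup of "concept|feature" -> response
# text; anything else gets `default`.
scripted_verifier <- function(name, responses, default = "False") {
  verifier(name, function(prompt) {
    pair <- novanorms:::prompt_pair(prompt)
    key <- paste(pair$concept, pair$feature, sep = "|")
    if (!is.null(responses[[key]])) responses[[key]] else default
  })
}

# Verifier that always raises, for failure-path tests.
failing_verifier <- function(name = "broken") {
  verifier(name, function(prompt) stop("backend unavailable"))
}
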