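# Synthetic truth matrices, sparse elicitation, simulated verifiers, and
# simulated triadic choosers.

test_that("degenerate probabilities give exact block or empty matrices", {
  cfg <- sim_config(
    n_concepts = 12L, n_features = 18L, n_categories = 3L,
    p_within = 1, p_across = 0, seed = 1L
  )
  truth <- simulate_truth_matrix(cfg)
  ccat <- attr(truth, "concept_category")
  fcat <- attr(truth, "feature_category")
  expect_identical(
    unname(truth$values == 1L),
    outer(unname(ccat), unname(fcat), `==`)
  )
  empty <- simulate_truth_matrix(sim_config(
    n_concepts = 5L, n_features = 5L, n_categories = 1L,
    p_within = 0, p_across = 0, seed = 2L
  ))
  expect_identical(sum(empty$values), 0L)
  expect_error(sim_config(p_within = 1.2), "probability")
})

test_that("ones count matches the block-structure expectation within 3 sigma", {
  cfg <- sim_config(seed = 303L) # 60 x 400, 6 blocks, .4 within / .02 across
  truth <- simulate_truth_matrix(cfg)
  ccat <- attr(truth, "concept_category")
  fcat <- attr(truth, "feature_category")
  n_within <- sum(outer(unname(ccat), unname(fcat), `==`))
  n_across <- length(ccat) * length(fcat) - n_within
  mu <- n_within * cfg$p_within + n_across * cfg$p_across
  sigma <- sqrt(
    n_within * cfg$p_within * (1 - cfg$p_within) +
      n_across * cfg$p_across * (1 - cfg$p_across)
  )
  expect_lt(abs(sum(truth$values) - mu), 3 * sigma)
})

test_that("elicitation keeps true cells at the configured rate and nothing else", {
  cfg <- sim_config(n_concepts = 30L, n_features = 200L, seed = 11L)
  truth <- simulate_truth_matrix(cfg)
  # limits
  expect_identical(simulate_elicitation(truth, 1, seed = 1L)$values, truth$values)
  expect_identical(sum(simulate_elicitation(truth, 0, seed = 1L)$values), 0L)
  # rate
  el <- simulate_elicitation(truth, 0.3, seed = 12L)
  expect_true(all(truth$values[el$values == 1L] == 1L)) # false cells never listed
  n_true <- sum(truth$values)
  expect_lt(abs(sum(el$values) - 0.3 * n_true), 3 * sqrt(n_true * 0.3 * 0.7))
  expect_true(all(el$provenance[el$values == 1L] == "elicited"))
})

test_that("a 1/35 listing rate reproduces the sparse-to-dense density regime", {
  cfg <- sim_config(seed = 21L)
  truth <- simulate_truth_matrix(cfg)
  el <- simulate_elicitation(truth, cfg$p_list, seed = 22L)
  ratio <- density_stats(el)$mean_features_per_concept /
    density_stats(truth)$mean_features_per_concept
  n_true <- sum(truth$values)
  se <- sqrt(n_true * cfg$p_list * (1 - cfg$p_list)) / n_true
  expect_lt(abs(ratio - 1 / 35), 3 * se)
})

test_that("simulated verifiers are seeded, order-independent, and rate-faithful", {
  truth <- simulate_truth_matrix(sim_config(
    n_concepts = 10L, n_features = 20L, n_categories = 1L,
    p_within = 0.5, p_across = 0.5, seed = 31L
  ))
  v <- make_simulated_verifier(truth, 0.8, 0.2, seed = 32L)
  p1 <- build_prompt("feature0001", "concept001")
  p2 <- build_prompt("feature0002", "concept002")
  r1 <- v$respond(p1)
  r2 <- v$respond(p2)
  # same answers regardless of query order or repetition
  expect_identical(v$respond(p2), r2)
  expect_identical(v$respond(p1), r1)
  expect_true(r1 %in% c("True", "False"))

  # perfect oracle: cascading it with itself changes nothing
  oracle <- make_simulated_verifier(truth, 1, 0, seed = 33L)
  all_pairs <- expand.grid(
    concept = unname(truth$concept_labels),
    feature = unname(truth$feature_labels),
    stringsAsFactors = FALSE
  )
  vt_single <- verify_pairs(all_pairs, oracle)
  vt_cascade <- cascade_verify(all_pairs, oracle, oracle)
  expect_identical(vt_single$decision, vt_cascade$decision)
  truth_vec <- truth$values[cbind(
    match(canonical_id(vt_single$concept), names(truth$concept_labels)),
    match(canonical_id(vt_single$feature), names(truth$feature_labels))
  )]
  expect_identical(vt_single$decision, truth_vec == 1L)

  # unknown pairs answer at the false-alarm rate (here 0)
  expect_identical(oracle$respond(build_prompt("made up", "unknown thing")), "False")
})

test_that("hit = fa yields verdicts carrying no signal (d-prime about 0)", {
  truth <- simulate_truth_matrix(sim_config(
    n_concepts = 40L, n_features = 50L, n_categories = 1L,
    p_within = 0.5, p_across = 0.5, seed = 41L
  ))
  null_v <- make_simulated_verifier(truth, 0.5, 0.5, seed = 42L)
  gold <- build_gold_set(simulate_gold_judgments(truth, 1500L, seed = 43L))
  vt <- verify_pairs(gold[, c("concept", "feature")], null_v)
  dp <- dprime(confusion_counts(gold, vt))
  # H and F both estimate 0.5; se of d' is about sqrt(2 * .25/(n/2)) / dnorm(0)
  se <- sqrt(2 * 0.25 / (nrow(gold) / 2)) / stats::dnorm(0)
  expect_lt(abs(dp$dprime), 4 * se)
})

test_that("cascade of independent verifiers obeys AND monotonicity in the rates", {
  truth <- simulate_truth_matrix(sim_config(
    n_concepts = 50L, n_features = 100L, n_categories = 1L,
    p_within = 0.5, p_across = 0.5, seed = 51L
  ))
  v1 <- make_simulated_verifier(truth, 0.9, 0.3, seed = 52L, name = "v1")
  v2 <- make_simulated_verifier(truth, 0.95, 0.05, seed = 53L, name = "v2")
  pairs <- expand.grid(
    concept = unname(truth$concept_labels),
    feature = unname(truth$feature_labels),
    stringsAsFactors = FALSE
  )
  vt1 <- verify_pairs(pairs, v1)
  vt2 <- verify_pairs(pairs, v2)
  vtc <- cascade_verify(pairs, v1, v2)
  # cascade positives = intersection of the component positive sets
  expect_identical(vtc$decision, vt1$decision & vt2$decision)
  truth_vec <- truth$values[cbind(
    match(canonical_id(vtc$concept), names(truth$concept_labels)),
    match(canonical_id(vtc$feature), names(truth$feature_labels))
  )] == 1L
  rate <- function(d, mask) sum(d & mask) / sum(mask)
  expect_lte(rate(vtc$decision, truth_vec), min(rate(vt1$decision, truth_vec), rate(vt2$decision, truth_vec)))
  expect_lte(rate(vtc$decision, !truth_vec), min(rate(vt1$decision, !truth_vec), rate(vt2$decision, !truth_vec)))
})

test_that("simulated triadic choices follow the logistic choice model", {
  d <- matrix(
    c(
      0, 0.30, 0.45, 0.9,
      0.30, 0, 0.5, 0.9,
      0.45, 0.5, 0, 0.9,
      0.9, 0.9, 0.9, 0
    ),
    4L, 4L,
    dimnames = list(c("t", "a", "b", "c"), c("t", "a", "b", "c"))
  )
  trip <- data.frame(
    id = "x", target = "t", option_a = "a", option_b = "b",
    stringsAsFactors = FALSE
  )
  # noiseless: everyone picks the nearer option
  ch0 <- simulate_triadic_choices(d, trip, n_participants = 20L, choice_noise = 0, seed = 1L)
  expect_true(all(ch0$choice == "a"))
  # moderate noise: frequency matches plogis((db - da)/noise)
  noise <- 0.1
  p_a <- stats::plogis((0.45 - 0.30) / noise)
  ch <- simulate_triadic_choices(d, trip, n_participants = 4000L, choice_noise = noise, seed = 2L)
  phat <- mean(ch$choice == "a")
  expect_lt(abs(phat - p_a), 4 * sqrt(p_a * (1 - p_a) / 4000))
  # huge noise: coin flip
  chN <- simulate_triadic_choices(d, trip, n_participants = 4000L, choice_noise = 1e6, seed = 3L)
  expect_lt(abs(mean(chN$choice == "a") - 0.5), 4 * sqrt(0.25 / 4000))
})

test_that("majority votes match the closed-form binomial vote probability", {
  d <- matrix(
    c(
      0, 0.35, 0.50, 0.9,
      0.35, 0, 0.6, 0.9,
      0.50, 0.6, 0, 0.9,
      0.9, 0.9, 0.9, 0
    ),
    4L, 4L,
    dimnames = list(c("t", "a", "b", "c"), c("t", "a", "b", "c"))
  )
  trip <- data.frame(
    id = "x", target = "t", option_a = "a", option_b = "b",
    stringsAsFactors = FALSE
  )
  noise <- 0.1
  p_a <- stats::plogis((0.50 - 0.35) / noise)
  n_part <- 31L
  p_majority <- 1 - stats::pbinom(15L, n_part, p_a) # P(>= 16 of 31 pick a)
  wins <- vapply(1:400, function(s) {
    ch <- simulate_triadic_choices(d, trip, n_participants = n_part, choice_noise = noise, seed = s)
    sum(ch$choice == "a") > n_part / 2
  }, logical(1L))
  expect_lt(abs(mean(wins) - p_majority), 4 * sqrt(p_majority * (1 - p_majority) / 400))
})

test_that("simulators are byte-reproducible under a fixed seed", {
  cfg <- sim_config(n_concepts = 20L, n_features = 40L, seed = 61L)
  t1 <- simulate_truth_matrix(cfg)
  t2 <- simulate_truth_matrix(cfg)
  expect_identical(t1$values, t2$values)
  e1 <- simulate_elicitation(t1, 0.2, seed = 62L)
  e2 <- simulate_elicitation(t1, 0.2, seed = 62L)
  expect_identical(e1$values, e2$values)
  j1 <- simulate_gold_judgments(t1, 50L, seed = 63L)
  j2 <- simulate_gold_judgments(t1, 50L, seed = 63L)
  expect_identical(j1, j2)
})
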