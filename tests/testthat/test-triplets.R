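# Cosine dissimilarity, Procrustes alignment, discrepancy ranking, divergent
# triplet generation, choice prediction, and agreement scoring.

test_that("cosine dissimilarity matches hand computations", {
  m <- norm_matrix(
    c("a", "b", "c", "d"), c("f1", "f2", "f3"),
    data.frame(
      concept = c("a", "a", "b", "b", "c", "c", "d"),
      feature = c("f1", "f2", "f1", "f3", "f1", "f2", "f3"),
      value = 1L, provenance = "elicited"
    )
  )
  d <- cosine_dissimilarity(m)
  expect_equal(d["a", "c"], 0) # identical rows
  expect_equal(d["a", "d"], 1) # disjoint rows
  expect_equal(d["a", "b"], 0.5) # (1,1,0) vs (1,0,1): cos = 1/2
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))

  empty_row <- norm_matrix(c("a", "b"), "f", data.frame(
    concept = "a", feature = "f", value = 1L, provenance = "elicited"
  ))
  expect_error(cosine_dissimilarity(empty_row), "zero feature vector.*b")
})

test_that("procrustes alignment is exact on identical and rescaled inputs", {
  set.seed(61)
  d1 <- random_dissimilarity(6L)
  a <- procrustes_align(d1, d1)
  expect_equal(a$disparity, 0, tolerance = 1e-12)
  expect_equal(unname(a$per_concept_discrepancy), rep(0, 6), tolerance = 1e-12)

  a2 <- procrustes_align(d1, 3 * d1)
  expect_equal(a2$disparity, 0, tolerance = 1e-12)

  expect_equal(sum(a$per_concept_discrepancy), a$disparity)
  d2 <- random_dissimilarity(6L)
  a3 <- procrustes_align(d1, d2)
  expect_equal(sum(a3$per_concept_discrepancy), a3$disparity)

  bad <- d2
  rownames(bad) <- colnames(bad) <- rev(rownames(d2))
  expect_error(procrustes_align(d1, bad), "alignment error")
  expect_error(
    procrustes_align(d1[1:2, 1:2], d2[1:2, 1:2]),
    "at least 3"
  )
})

test_that("procrustes disparity agrees with vegan and beats random rotations", {
  skip_if_not_installed("vegan")
  set.seed(62)
  for (rep in 1:5) {
    n <- sample(4:8, 1L)
    d1 <- random_dissimilarity(n)
    d2 <- random_dissimilarity(n)
    ours <- procrustes_align(d1, d2)
    # vegan rotates its second argument onto its first
    ref <- vegan::procrustes(d2, d1, symmetric = TRUE)
    expect_equal(ours$disparity, ref$ss, tolerance = 1e-10)

    # optimality: no random orthogonal transform (with its own optimal
    # scale) does better
    X <- novanorms:::normalize_configuration(d1)
    Y <- novanorms:::normalize_configuration(d2)
    for (k in 1:40) {
      Q <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
      s <- sum(diag(crossprod(X %*% Q, Y)))
      resid <- sum((Y - max(s, 0) * (X %*% Q))^2)
      expect_gte(resid, ours$disparity - 1e-12)
    }
  }
})

test_that("discrepancy ranking surfaces a perturbed concept first", {
  set.seed(63)
  d1 <- random_dissimilarity(8L)
  d2 <- d1
  d2["w03", ] <- d2["w03", ] + 0.4
  d2[, "w03"] <- d2[, "w03"] + 0.4
  d2["w03", "w03"] <- 0
  al <- procrustes_align(d1, d2)
  ranked <- rank_discrepant_concepts(al)
  expect_identical(ranked[1L], "w03")
  # order matches an independent recomputation of row residuals
  resid <- rowSums((al$target - al$aligned_source)^2)
  expect_identical(ranked, names(resid)[order(-resid, names(resid))])

  # all-equal residuals fall back to lexicographic order
  flat <- al
  flat$per_concept_discrepancy[] <- 0.5
  expect_identical(rank_discrepant_concepts(flat), sort(rownames(d1)))
})

test_that("identical spaces generate no triplets", {
  set.seed(64)
  d <- random_dissimilarity(7L)
  ts <- generate_divergent_triplets(d, d, seed = 1L)
  expect_identical(nrow(ts), 0L)
})

test_that("a single hand-built divergent triple is found exactly", {
  labels <- c("accordion", "flute", "geyser", "rock", "tuba", "violin")
  n <- length(labels)
  base <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(base) <- 0
  d1 <- base
  d2 <- base
  # space 1: accordion closer to geyser; space 2: accordion closer to flute
  d1["accordion", "flute"] <- d1["flute", "accordion"] <- 0.9
  d1["accordion", "geyser"] <- d1["geyser", "accordion"] <- 0.3
  d2["accordion", "flute"] <- d2["flute", "accordion"] <- 0.2
  d2["accordion", "geyser"] <- d2["geyser", "accordion"] <- 0.8
  ts <- generate_divergent_triplets(d1, d2, per_target_quota = 5L, seed = 2L)
  bf <- brute_force_triplets(d1, d2)
  expect_identical(nrow(ts), nrow(bf))
  expect_identical(
    sort(ts$id),
    sort(paste(bf$target, bf$option_a, bf$option_b, sep = "|"))
  )
  tr <- ts[ts$target == "accordion", ]
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$option_a, "flute") # closer in space 2
  expect_identical(tr$option_b, "geyser") # closer in space 1
  expect_identical(tr$closer_in_space1, "geyser")
  expect_equal(tr$score, min(0.9 - 0.3, 0.8 - 0.2))
})

test_that("emitted triplets satisfy strict divergence against the raw matrices", {
  set.seed(65)
  for (rep in 1:5) {
    d1 <- random_dissimilarity(9L)
    d2 <- random_dissimilarity(9L)
    ts <- generate_divergent_triplets(d1, d2, per_target_quota = 3L, seed = rep)
    for (i in seq_len(nrow(ts))) {
      t <- ts$target[i]
      a <- ts$option_a[i]
      b <- ts$option_b[i]
      expect_gt(d1[t, a] - d1[t, b], 1e-12) # space 1: closer to b
      expect_gt(d2[t, b] - d2[t, a], 1e-12) # space 2: closer to a
      expect_equal(ts$score[i], min(d1[t, a] - d1[t, b], d2[t, b] - d2[t, a]))
    }
  }
})

test_that("triplet output is invariant to concept ordering of the inputs", {
  set.seed(66)
  d1 <- random_dissimilarity(8L)
  d2 <- random_dissimilarity(8L)
  perm <- sample(8L)
  ts1 <- generate_divergent_triplets(d1, d2, seed = 3L)
  ts2 <- generate_divergent_triplets(d1[perm, perm], d2[perm, perm], seed = 3L)
  expect_identical(ts1$id, ts2$id)
  expect_equal(ts1$score, ts2$score)
})

test_that("per-target quota and global cap are honored", {
  set.seed(67)
  d1 <- random_dissimilarity(10L)
  d2 <- random_dissimilarity(10L)
  ts <- generate_divergent_triplets(d1, d2, per_target_quota = 2L, seed = 4L)
  expect_true(all(table(ts$target) <= 2L))
  capped <- generate_divergent_triplets(d1, d2,
    per_target_quota = 2L, total = 5L, seed = 4L
  )
  expect_identical(nrow(capped), 5L)
  # the cap keeps the globally highest-scoring triplets
  expect_equal(sort(capped$score), sort(ts$score, decreasing = TRUE)[1:5][5:1])
})

test_that("choice prediction picks the nearer option and flags ties", {
  d <- matrix(
    c(
      0, 0.2, 0.5, 0.5,
      0.2, 0, 0.3, 0.4,
      0.5, 0.3, 0, 0.6,
      0.5, 0.4, 0.6, 0
    ),
    4L, 4L,
    dimnames = list(c("t", "a", "b", "c"), c("t", "a", "b", "c"))
  )
  trip <- data.frame(
    id = c("x", "y"), target = "t",
    option_a = c("a", "b"), option_b = c("b", "c"),
    stringsAsFactors = FALSE
  )
  pred <- predict_choices(d, trip)
  expect_identical(pred$choice[1L], "a") # 0.2 vs 0.5
  expect_identical(pred$choice[2L], NA_character_) # equidistant options tie
  expect_true(pred$tie[2L])
  expect_error(
    predict_choices(d, data.frame(id = "z", target = "t", option_a = "nope", option_b = "a")),
    "missing"
  )
})

test_that("predictions on the generating matrices reproduce the stored orientation", {
  set.seed(68)
  d1 <- random_dissimilarity(9L)
  d2 <- random_dissimilarity(9L)
  ts <- generate_divergent_triplets(d1, d2, per_target_quota = 3L, seed = 5L)
  p1 <- predict_choices(d1, ts)
  p2 <- predict_choices(d2, ts)
  expect_identical(p1$choice, ts$option_b)
  expect_identical(p1$choice, ts$closer_in_space1)
  expect_identical(p2$choice, ts$option_a)
})

test_that("agreement scoring reproduces the exact binomial and paired-t oracles", {
  # 100 triplets, space-2 predictions agree with the majority on 60
  ids <- sprintf("t%03d", 1:100)
  trip_pred2 <- data.frame(
    id = ids, choice = ifelse(seq_along(ids) <= 60, "right", "wrong"),
    tie = FALSE, stringsAsFactors = FALSE
  )
  trip_predb <- data.frame(
    id = ids, choice = "right", tie = FALSE, stringsAsFactors = FALSE
  )
  human <- data.frame(
    participant = "p1", triplet = ids, choice = "right",
    stringsAsFactors = FALSE
  )
  res <- score_agreement(human, trip_pred2, trip_predb)
  expect_equal(res$agree_space2, 0.6)
  expect_equal(res$agree_baseline, 1.0)
  expect_equal(res$binomial_p, binom_p_oracle(60L, 100L), tolerance = 1e-12)
  expect_equal(res$binomial_p, 0.056887, tolerance = 1e-4)
  expect_identical(res$df, 99L)

  # indicators (1,1,1,0) vs (0,0,1,0): t = 1.732, df = 3
  ids4 <- sprintf("q%d", 1:4)
  maj <- c("a", "a", "a", "a")
  pred2 <- data.frame(id = ids4, choice = c("a", "a", "a", "b"), tie = FALSE)
  predb <- data.frame(id = ids4, choice = c("b", "b", "a", "b"), tie = FALSE)
  human4 <- data.frame(participant = "p1", triplet = ids4, choice = maj)
  res4 <- score_agreement(human4, pred2, predb)
  expect_equal(res4$paired_t, 1.7320508, tolerance = 1e-6)
  expect_identical(res4$df, 3L)

  # majority-vote ties are excluded and reported
  human_tie <- rbind(
    data.frame(participant = "p1", triplet = "q1", choice = "a"),
    data.frame(participant = "p2", triplet = "q1", choice = "b"),
    data.frame(participant = "p1", triplet = "q2", choice = "a"),
    data.frame(participant = "p2", triplet = "q2", choice = "a")
  )
  res_tie <- score_agreement(
    human_tie,
    data.frame(id = c("q1", "q2"), choice = "a", tie = FALSE),
    data.frame(id = c("q1", "q2"), choice = "b", tie = FALSE)
  )
  expect_identical(res_tie$n_vote_ties, 1L)
  expect_identical(res_tie$n_triplets, 1L)
})

test_that("triplet sets and choices round-trip through their file formats", {
  set.seed(69)
  d1 <- random_dissimilarity(7L)
  d2 <- random_dissimilarity(7L)
  ts <- generate_divergent_triplets(d1, d2, seed = 6L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_triplets(ts, path)
  back <- read_triplets(path)
  expect_identical(back$target, ts$target)
  expect_identical(back$option_a, ts$option_a)
  expect_identical(back$option_b, ts$option_b)
  expect_equal(back$score, ts$score)

  ch <- simulate_triadic_choices(d2, ts, n_participants = 3L, choice_noise = 0.1, seed = 7L)
  cpath <- withr::local_tempfile(fileext = ".jsonl")
  write_choices(ch, cpath)
  back_ch <- read_choices(cpath)
  expect_identical(back_ch, ch)
})
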