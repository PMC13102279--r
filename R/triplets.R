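# Triadic similarity benchmarking: cosine dissimilarity between concept
# feature vectors, Procrustes alignment of two dissimilarity matrices,
# discrepancy ranking, construction of maximally disagreeing triplets (the
# two spaces predict opposite nearest options), choice prediction, and
# agreement scoring against human majority votes.

#' Cosine dissimilarity matrix between concept rows
#'
#' Entry (i, k) is `1 - cos(row_i, row_k)`; symmetric, zero diagonal, entries
#' in [0, 2].
#'
#' @param m a `norm_matrix`, or a numeric matrix with concepts as named rows
#'   (e.g. a word-embedding table).
#' @return a square symmetric numeric matrix with concept ids as dimnames.
#' @export
cosine_dissimilarity <- function(m) {
  if (inherits(m, "norm_matrix")) {
    X <- m$values
  } else {
    X <- as.matrix(m)
    if (is.null(rownames(X))) stopf("matrix rows must be named by concept")
    rownames(X) <- canonical_id(rownames(X))
  }
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    stopf("zero feature vector for concept: %s", rownames(X)[which(nrm == 0)[1L]])
  }
  Xn <- X / nrm
  D <- 1 - tcrossprod(Xn)
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  D[D > 2] <- 2
  diag(D) <- 0
  D
}

validate_dissimilarity <- function(d, tol = 1e-9) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stopf("dissimilarity matrix must be square")
  if (is.null(rownames(d))) stopf("dissimilarity matrix must have concept labels")
  if (!all(is.finite(d))) stopf("non-finite dissimilarity entries")
  if (max(abs(d - t(d))) > tol) stopf("dissimilarity matrix not symmetric")
  if (max(abs(diag(d))) > tol) stopf("dissimilarity diagonal not zero")
  d
}

#' Ordinary Procrustes alignment of two dissimilarity matrices
#'
#' Both matrices are treated as point configurations (rows as points in
#' n-dimensional space). Each configuration is centered and scaled to unit
#' total sum of squares; the first is then rotated (reflections allowed, via
#' the SVD closed form) and isotropically rescaled to best fit the second.
#' Disparity is the residual sum of squares after alignment, decomposed into
#' one squared residual per concept.
#'
#' @param d1,d2 square symmetric dissimilarity matrices with identical
#'   concept labels in identical order; at least 3 concepts.
#' @param allow_reflection if `FALSE`, the rotation is constrained to
#'   determinant +1 (default `TRUE`).
#' @return object of class `procrustes_alignment`: list with
#'   `aligned_source` (transformed configuration 1), `target` (normalized
#'   configuration 2), `rotation`, `scale`, `disparity` and
#'   `per_concept_discrepancy` (named, `sum == disparity`).
#' @export
procrustes_align <- function(d1, d2, allow_reflection = TRUE) {
  d1 <- validate_dissimilarity(d1)
  d2 <- validate_dissimilarity(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    stopf("alignment error: concept labels differ or are ordered differently")
  }
  if (nrow(d1) < 3L) stopf("alignment requires at least 3 concepts")
  X <- normalize_configuration(d1)
  Y <- normalize_configuration(d2)
  sv <- svd(crossprod(X, Y))
  R <- sv$u %*% t(sv$v)
  sings <- sv$d
  if (!allow_reflection && det(R) < 0) {
    # Flip the smallest singular direction to stay in SO(n).
    flip <- diag(ncol(R))
    flip[ncol(R), ncol(R)] <- -1
    R <- sv$u %*% flip %*% t(sv$v)
    sings[length(sings)] <- -sings[length(sings)]
  }
  s <- sum(sings) # optimal isotropic scale for unit-SS configurations
  aligned <- s * (X %*% R)
  resid <- Y - aligned
  per_concept <- rowSums(resid^2)
  names(per_concept) <- rownames(d1)
  structure(
    list(
      aligned_source = aligned, target = Y, rotation = R, scale = s,
      disparity = sum(per_concept), per_concept_discrepancy = per_concept
    ),
    class = "procrustes_alignment"
  )
}

normalize_configuration <- function(d) {
  X <- sweep(d, 2L, colMeans(d))
  ss <- sum(X^2)
  if (ss <= 0) stopf("degenerate configuration: zero variance")
  X / sqrt(ss)
}

#' @export
print.procrustes_alignment <- function(x, ...) {
  cat(sprintf(
    "procrustes_alignment: %d concepts, disparity %.6f, scale %.4f\n",
    length(x$per_concept_discrepancy), x$disparity, x$scale
  ))
  invisible(x)
}

#' Rank concepts by alignment discrepancy
#'
#' Concepts sorted by per-concept squared residual, largest first (the
#' concepts whose distances to the other concepts differ most between the
#' two spaces); ties broken lexicographically.
#'
#' @param alignment a [procrustes_align()] result.
#' @return character vector of concept labels.
#' @export
rank_discrepant_concepts <- function(alignment) {
  d <- alignment$per_concept_discrepancy
  names(d)[order(-d, names(d), method = "radix")]
}

#' Generate maximally disagreeing triadic triplets
#'
#' For each target concept `t`, enumerates option pairs `(a, b)` on which
#' the two spaces disagree about which option is nearer: the triplet is
#' oriented so that in space 1 the target is strictly closer to `option_b`,
#' and in space 2 strictly closer to `option_a`. Each triplet is scored by
#' the smaller of its two divergence margins (so near-ties in either space
#' score low), the top `per_target_quota` pairs are kept per target, and an
#' optional global `total` keeps only the highest-scoring triplets overall.
#' Left/right presentation order is randomized by `seed`; the divergence
#' orientation is recorded in `closer_in_space1`.
#'
#' @param d1,d2 dissimilarity matrices on identical labels.
#' @param per_target_quota max triplets per target (default 2).
#' @param total optional global cap on the number of triplets.
#' @param seed integer seed for left/right randomization.
#' @param min_margin strictness margin; both divergence margins must exceed
#'   it (default 1e-12) so floating-point ties never produce triplets.
#' @return object of class `triplet_set`: a data frame with columns `id`,
#'   `target`, `option_a` (closer in space 2), `option_b` (closer in space
#'   1), `margin_1`, `margin_2`, `score`, `option_left`, `option_right`,
#'   `closer_in_space1`; attribute `per_target_counts`.
#' @export
generate_divergent_triplets <- function(d1, d2, per_target_quota = 2L, total = NULL,
                                        seed = 1L, min_margin = 1e-12) {
  d1 <- validate_dissimilarity(d1)
  d2 <- validate_dissimilarity(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    stopf("matrices must share identical concept labels in identical order")
  }
  if (!is_count(per_target_quota) || per_target_quota < 1L) stopf("per_target_quota must be >= 1")
  labels <- rownames(d1)
  n <- length(labels)
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    others <- setdiff(seq_len(n), t)
    if (length(others) < 2L) next
    pr <- utils::combn(others, 2L)
    i <- pr[1L, ]
    k <- pr[2L, ]
    delta1 <- d1[t, i] - d1[t, k] # >0: space 1 has target closer to k
    delta2 <- d2[t, i] - d2[t, k]
    fwd <- delta1 > min_margin & delta2 < -min_margin # a = i, b = k
    rev <- delta1 < -min_margin & delta2 > min_margin # a = k, b = i
    if (!any(fwd) && !any(rev)) next
    a <- c(i[fwd], k[rev])
    b <- c(k[fwd], i[rev])
    m1 <- abs(c(delta1[fwd], delta1[rev]))
    m2 <- abs(c(delta2[fwd], delta2[rev]))
    score <- pmin(m1, m2)
    ord <- order(-score, labels[a], labels[b], method = "radix")
    keep <- utils::head(ord, per_target_quota)
    rows[[t]] <- data.frame(
      target = labels[t], option_a = labels[a[keep]], option_b = labels[b[keep]],
      margin_1 = m1[keep], margin_2 = m2[keep], score = score[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(
      target = character(), option_a = character(), option_b = character(),
      margin_1 = numeric(), margin_2 = numeric(), score = numeric(),
      stringsAsFactors = FALSE
    )
  }
  ord <- order(-out$score, out$target, out$option_a, out$option_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  if (!is.null(total)) out <- utils::head(out, total)
  # Back to deterministic (target, options) order for stable ids.
  ord <- order(out$target, out$option_a, out$option_b, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$id <- if (nrow(out)) paste(out$target, out$option_a, out$option_b, sep = "|") else character()
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  flip <- if (nrow(out)) stats::runif(nrow(out)) < 0.5 else logical()
  out$option_left <- ifelse(flip, out$option_b, out$option_a)
  out$option_right <- ifelse(flip, out$option_a, out$option_b)
  out$closer_in_space1 <- out$option_b
  counts <- table(factor(out$target, levels = sort(labels, method = "radix")))
  class(out) <- c("triplet_set", "data.frame")
  attr(out, "per_target_counts") <- counts
  out
}

#' @export
print.triplet_set <- function(x, ...) {
  cat(sprintf(
    "triplet_set: %d triplets over %d targets\n",
    nrow(x), length(unique(x$target))
  ))
  invisible(x)
}

#' Predict triadic choices from a dissimilarity matrix
#'
#' For each triplet, picks whichever option lies closer to the target in the
#' given space. Exact ties are flagged (`tie = TRUE`, `choice = NA`) and are
#' excluded from agreement scoring.
#'
#' @param space a dissimilarity matrix containing all triplet concepts.
#' @param triplets a [generate_divergent_triplets()] result (or compatible
#'   data frame with `id`, `target`, `option_a`, `option_b`).
#' @return `data.frame` with columns `id`, `choice`, `tie`.
#' @export
predict_choices <- function(space, triplets) {
  space <- validate_dissimilarity(space)
  labs <- rownames(space)
  need <- unique(c(triplets$target, triplets$option_a, triplets$option_b))
  missing <- setdiff(canonical_id(need), canonical_id(labs))
  if (length(missing)) stopf("concept missing from space: %s", missing[1L])
  ti <- match(canonical_id(triplets$target), canonical_id(labs))
  ai <- match(canonical_id(triplets$option_a), canonical_id(labs))
  bi <- match(canonical_id(triplets$option_b), canonical_id(labs))
  da <- space[cbind(ti, ai)]
  db <- space[cbind(ti, bi)]
  tie <- da == db
  choice <- ifelse(da < db, triplets$option_a, triplets$option_b)
  choice[tie] <- NA_character_
  data.frame(id = triplets$id, choice = choice, tie = tie, stringsAsFactors = FALSE)
}

#' Score prediction agreement with human majority votes
#'
#' Takes per-participant choices, forms the majority vote per triplet
#' (vote ties excluded, exclusion count reported), and computes the fraction
#' of voted triplets on which each prediction list matches the majority.
#' Reports an exact two-sided binomial test of the space-2 agreement against
#' chance (0.5) and a paired t-test on the per-triplet agreement indicators
#' (space 2 minus baseline), df = n - 1.
#'
#' @param human_choices `data.frame` with columns `triplet` (triplet id),
#'   `participant`, `choice`.
#' @param space2_pred,baseline_pred [predict_choices()] outputs aligned to
#'   the same triplets.
#' @return object of class `agreement_result`: list with `n_triplets`,
#'   `n_vote_ties`, `agree_space2`, `agree_baseline`, `binomial_p`,
#'   `paired_t`, `df`, `t_p`.
#' @export
score_agreement <- function(human_choices, space2_pred, baseline_pred) {
  if (nrow(human_choices) == 0L) stopf("no human choices supplied")
  votes <- split(human_choices$choice, human_choices$triplet)
  majority <- vapply(votes, function(ch) {
    tab <- sort(table(ch), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) NA_character_ else names(tab)[1L]
  }, character(1L))
  n_vote_ties <- sum(is.na(majority))
  majority <- majority[!is.na(majority)]
  p2 <- setNames(space2_pred$choice, space2_pred$id)
  pb <- setNames(baseline_pred$choice, baseline_pred$id)
  ids <- names(majority)
  if (!all(ids %in% names(p2)) || !all(ids %in% names(pb))) {
    stopf("prediction lists do not cover all voted triplets")
  }
  usable <- !is.na(p2[ids]) & !is.na(pb[ids])
  ids <- ids[usable]
  n <- length(ids)
  if (n == 0L) stopf("no triplets left after tie exclusion")
  ind2 <- as.integer(canonical_id(p2[ids]) == canonical_id(majority[ids]))
  indb <- as.integer(canonical_id(pb[ids]) == canonical_id(majority[ids]))
  k2 <- sum(ind2)
  bt <- stats::binom.test(k2, n, p = 0.5, alternative = "two.sided")
  diffs <- ind2 - indb
  if (n >= 2L && stats::sd(diffs) > 0) {
    tt <- stats::t.test(ind2, indb, paired = TRUE)
    paired_t <- unname(tt$statistic)
    t_p <- tt$p.value
  } else if (n >= 2L && mean(diffs) != 0) {
    # perfect separation: zero-variance nonzero differences; the t statistic
    # diverges, so report its limit rather than NA
    paired_t <- sign(mean(diffs)) * Inf
    t_p <- 0
  } else {
    paired_t <- NA_real_
    t_p <- NA_real_
  }
  structure(
    list(
      n_triplets = n, n_vote_ties = n_vote_ties,
      agree_space2 = k2 / n, agree_baseline = mean(indb),
      binomial_p = bt$p.value,
      paired_t = paired_t, df = n - 1L, t_p = t_p
    ),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "agreement over %d triplets (%d vote ties excluded):\n",
      "  space 2: %.2f%% (exact binomial vs 0.5: p = %.3g)\n",
      "  baseline: %.2f%%\n",
      "  paired t(%d) = %.3f, p = %.3g\n"
    ),
    x$n_triplets, x$n_vote_ties,
    100 * x$agree_space2, x$binomial_p,
    100 * x$agree_baseline,
    x$df, x$paired_t, x$t_p
  ))
  invisible(x)
}

#' Write / read a triplet set as TSV
#'
#' Columns `target`, `option_left`, `option_right`, `closer_in_space1`,
#' `score`.
#' @param triplets a `triplet_set`.
#' @param path file path.
#' @export
write_triplets <- function(triplets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    "target\toption_left\toption_right\tcloser_in_space1\tscore",
    sprintf(
      "%s\t%s\t%s\t%s\t%s",
      triplets$target, triplets$option_left, triplets$option_right,
      triplets$closer_in_space1,
      format(triplets$score, digits = 17, trim = TRUE, scientific = FALSE)
    )
  )
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("target", "option_left", "option_right", "closer_in_space1", "score")
  if (!all(req %in% names(df))) stopf("triplet file needs columns %s", paste(req, collapse = ", "))
  option_b <- df$closer_in_space1
  option_a <- ifelse(df$option_left == option_b, df$option_right, df$option_left)
  out <- data.frame(
    target = df$target, option_a = option_a, option_b = option_b,
    margin_1 = NA_real_, margin_2 = NA_real_, score = as.numeric(df$score),
    id = paste(df$target, option_a, option_b, sep = "|"),
    option_left = df$option_left, option_right = df$option_right,
    closer_in_space1 = df$closer_in_space1, stringsAsFactors = FALSE
  )
  class(out) <- c("triplet_set", "data.frame")
  out
}

#' Read a word-embedding table (`word<TAB>v1,v2,...`) as a matrix
#'
#' Compatible with common pretrained-vector text dumps; the result can be
#' passed to [cosine_dissimilarity()] as a baseline semantic space.
#'
#' @param path file path.
#' @return numeric matrix with words as row names.
#' @export
read_word_vectors <- function(path) {
  emb <- read_embedding_table(path)
  v <- emb$vectors
  rownames(v) <- emb$phrases
  v
}

#' Simulated-participant triadic choices
#'
#' Each participant-triplet choice is drawn independently with probability of
#' picking `option_a` equal to `plogis((d(t, b) - d(t, a)) / choice_noise)`
#' in the reference space; `choice_noise = 0` degenerates to deterministic
#' nearest-option responding.
#'
#' @param space reference dissimilarity matrix (the space assumed to drive
#'   the choices).
#' @param triplets a `triplet_set`.
#' @param n_participants number of simulated raters.
#' @param choice_noise logistic scale on the distance difference (>= 0).
#' @param seed integer seed.
#' @return `data.frame` with columns `participant`, `triplet`, `choice`.
#' @export
simulate_triadic_choices <- function(space, triplets, n_participants, choice_noise, seed) {
  space <- validate_dissimilarity(space)
  if (!is_count(n_participants) || n_participants < 1L) stopf("n_participants must be >= 1")
  if (!is.numeric(choice_noise) || choice_noise < 0) stopf("choice_noise must be >= 0")
  labs <- canonical_id(rownames(space))
  ti <- match(canonical_id(triplets$target), labs)
  ai <- match(canonical_id(triplets$option_a), labs)
  bi <- match(canonical_id(triplets$option_b), labs)
  if (anyNA(ti) || anyNA(ai) || anyNA(bi)) stopf("space does not cover all triplet concepts")
  da <- space[cbind(ti, ai)]
  db <- space[cbind(ti, bi)]
  p_a <- if (choice_noise == 0) as.numeric(da < db) + 0.5 * (da == db) else stats::plogis((db - da) / choice_noise)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nt <- nrow(triplets)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    pick_a <- stats::runif(nt) < p_a
    rows[[p]] <- data.frame(
      participant = sprintf("sim%03d", p),
      triplet = triplets$id,
      choice = ifelse(pick_a, triplets$option_a, triplets$option_b),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Write / read triadic choices as JSONL (`participant`, `triplet`, `choice`)
#' @param choices `data.frame` with those columns.
#' @param path file path.
#' @export
write_choices <- function(choices, path) {
  recs <- lapply(seq_len(nrow(choices)), function(i) {
    list(
      participant = choices$participant[i],
      triplet = choices$triplet[i],
      choice = choices$choice[i]
    )
  })
  write_jsonl(recs, path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  recs <- read_jsonl(path)
  data.frame(
    participant = vapply(recs, function(r) as.character(r$participant), character(1L)),
    triplet = vapply(recs, function(r) as.character(r$triplet), character(1L)),
    choice = vapply(recs, function(r) as.character(r$choice), character(1L)),
    stringsAsFactors = FALSE
  )
}
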