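# Near-duplicate feature collapsing: cluster feature phrases by embedding
# similarity (complete linkage under cosine similarity, so every within-
# cluster pair clears the threshold), merge matrix columns by logical OR, and
# subsample the feature inventory.

#' Build a phrase embedding table
#'
#' The embedding source is a pluggable contract: phrases in, one fixed-length
#' real vector per phrase out. Any source (sentence-embedding model, hashing
#' trick, pre-computed table) is acceptable.
#'
#' @param phrases character vector of feature phrases (unique).
#' @param vectors numeric matrix, one row per phrase, `ncol >= 2`, finite.
#' @return object of class `embedding_table`.
#' @export
embedding_table <- function(phrases, vectors) {
  phrases <- as.character(phrases)
  if (anyDuplicated(phrases)) stopf("duplicate phrase in embedding table")
  vectors <- as.matrix(vectors)
  if (length(phrases) != nrow(vectors)) stopf("one vector per phrase required")
  if (ncol(vectors) < 2L) stopf("embedding dimension must be >= 2")
  if (!all(is.finite(vectors))) stopf("non-finite embedding entries")
  rownames(vectors) <- phrases
  structure(list(phrases = phrases, vectors = vectors), class = "embedding_table")
}

#' Deterministic hashing-based toy embedder
#'
#' Maps each phrase to a fixed-length vector by hashing its character
#' trigrams into buckets and counting. Deterministic, requires no model
#' access; phrases sharing most trigrams land close in cosine similarity.
#' Intended for tests and demonstrations, not as a linguistic claim.
#'
#' @param dim embedding dimension (default 32).
#' @return a function: character vector of phrases -> [embedding_table()].
#' @export
hash_embedder <- function(dim = 32L) {
  dim <- as.integer(dim)
  if (dim < 2L) stopf("dim must be >= 2")
  function(phrases) {
    phrases <- as.character(phrases)
    vecs <- matrix(0, length(phrases), dim)
    for (i in seq_along(phrases)) {
      s <- paste0("^", canonical_id(phrases[i]), "$")
      n <- nchar(s)
      if (n >= 3L) {
        for (k in seq_len(n - 2L)) {
          g <- substr(s, k, k + 2L)
          b <- (string_hash31(7L, g) %% dim) + 1L
          vecs[i, b] <- vecs[i, b] + 1
        }
      } else {
        vecs[i, (string_hash31(7L, s) %% dim) + 1L] <- 1
      }
    }
    embedding_table(phrases, vecs)
  }
}

#' Write / read an embedding table (`phrase<TAB>v1,v2,...`)
#' @param emb an `embedding_table`.
#' @param path file path.
#' @return `path` (writer) or an `embedding_table` (reader).
#' @export
write_embedding_table <- function(emb, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  vals <- apply(emb$vectors, 1L, function(v) paste(format(v, digits = 17, trim = TRUE, scientific = FALSE), collapse = ","))
  writeLines(enc2utf8(sprintf("%s\t%s", emb$phrases, vals)), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_embedding_table
#' @export
read_embedding_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stopf("parse error: expected phrase<TAB>values")
  phrases <- vapply(parts, `[[`, character(1L), 1L)
  vecs <- lapply(parts, function(p) as.numeric(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  d <- unique(lengths(vecs))
  if (length(d) != 1L) stopf("parse error: inconsistent embedding dimension")
  embedding_table(phrases, do.call(rbind, vecs))
}

#' Cluster feature phrases by embedding similarity
#'
#' Agglomerative grouping with complete linkage under cosine similarity: two
#' phrases share a cluster only if *every* within-cluster pair has cosine
#' similarity at or above `similarity_threshold`. At threshold 1 only
#' exactly-collinear vectors merge. Deterministic given the inputs.
#'
#' @param embeddings an [embedding_table()].
#' @param similarity_threshold cosine similarity in (0, 1]; default 0.95, a
#'   conservative criterion that merges rewordings while keeping close
#'   synonyms apart.
#' @param counts optional named numeric vector of elicitation frequencies per
#'   phrase; the cluster representative is its most frequent member phrase,
#'   ties (and the default, no counts) broken lexicographically.
#' @return object of class `feature_cluster_map`: list with `assignments`
#'   (named character, phrase -> cluster id) and `representatives` (named
#'   character, cluster id -> canonical phrase).
#' @export
cluster_features <- function(embeddings, similarity_threshold = 0.95, counts = NULL) {
  if (!inherits(embeddings, "embedding_table")) stopf("embeddings must be an embedding_table")
  if (!is.numeric(similarity_threshold) || length(similarity_threshold) != 1L ||
    similarity_threshold <= 0 || similarity_threshold > 1) {
    stopf("similarity_threshold must be in (0, 1]")
  }
  phrases <- embeddings$phrases
  if (length(phrases) == 0L) stopf("at least one phrase required")
  X <- embeddings$vectors
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    stopf("degenerate zero-norm vector for phrase: %s", phrases[which(nrm == 0)[1L]])
  }
  if (length(phrases) == 1L) {
    membership <- setNames(1L, phrases)
  } else {
    Xn <- X / nrm
    S <- tcrossprod(Xn)
    D <- 1 - S
    D[D < 0] <- 0
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    # Small tolerance so threshold 1 still merges exactly-collinear vectors
    # whose computed cosine is 1 minus floating-point dust.
    membership <- stats::cutree(hc, h = (1 - similarity_threshold) + 1e-12)
    names(membership) <- phrases
  }
  finalize_cluster_map(membership, counts)
}

finalize_cluster_map <- function(membership, counts = NULL) {
  reps <- vapply(split(names(membership), membership), function(members) {
    if (!is.null(counts)) {
      f <- counts[members]
      f[is.na(f)] <- 0
      members <- members[f == max(f)]
    }
    sort(members, method = "radix")[1L]
  }, character(1L))
  # Stable, readable cluster ids ordered by representative phrase.
  ord <- order(unname(reps), method = "radix")
  ids <- sprintf("c%0*d", nchar(length(ord)), seq_along(ord))
  id_of_raw <- setNames(ids, names(reps)[ord])
  assignments <- setNames(unname(id_of_raw[as.character(membership)]), names(membership))
  representatives <- setNames(unname(reps[ord]), ids)
  structure(
    list(assignments = assignments, representatives = representatives),
    class = "feature_cluster_map"
  )
}

#' @export
print.feature_cluster_map <- function(x, ...) {
  cat(sprintf(
    "feature_cluster_map: %d phrases in %d clusters\n",
    length(x$assignments), length(x$representatives)
  ))
  invisible(x)
}

#' Write / read a cluster map (`phrase<TAB>cluster_id<TAB>representative`)
#' @param clusters a `feature_cluster_map`.
#' @param path file path.
#' @export
write_cluster_map <- function(clusters, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  ph <- sort(names(clusters$assignments), method = "radix")
  cid <- clusters$assignments[ph]
  writeLines(
    enc2utf8(sprintf("%s\t%s\t%s", ph, cid, clusters$representatives[cid])),
    con,
    sep = "\n", useBytes = TRUE
  )
  invisible(path)
}

#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L)) stopf("parse error: expected 3 tab-separated fields")
  assignments <- setNames(
    vapply(parts, `[[`, character(1L), 2L),
    vapply(parts, `[[`, character(1L), 1L)
  )
  rep_rows <- vapply(parts, `[[`, character(1L), 3L)
  representatives <- tapply(rep_rows, unname(assignments), `[[`, 1L)
  structure(
    list(assignments = assignments, representatives = representatives[sort(names(representatives), method = "radix")]),
    class = "feature_cluster_map"
  )
}

#' Merge norm-matrix features by cluster
#'
#' Collapses feature columns that share a cluster into one column per
#' cluster: merged value is the logical OR of the member columns; a merged 1
#' is `"elicited"` if any contributing member cell was elicited, else
#' `"imputed"`; the column label is the cluster representative.
#'
#' @param m a `norm_matrix`; every feature phrase must appear in `clusters`.
#' @param clusters a [cluster_features()] map.
#' @return a `norm_matrix` with one column per cluster present in `m`.
#' @export
merge_features <- function(m, clusters) {
  validate_norm_matrix(m)
  phrases <- unname(m$feature_labels)
  cid <- clusters$assignments[phrases]
  if (anyNA(cid)) {
    stopf("feature not present in cluster map: %s", phrases[which(is.na(cid))[1L]])
  }
  present <- sort(unique(unname(cid)), method = "radix")
  rep_labels <- clusters$representatives[present]
  out <- norm_matrix(unname(m$concept_labels), unname(rep_labels))
  for (k in seq_along(present)) {
    members <- which(cid == present[k])
    vals <- m$values[, members, drop = FALSE]
    prov <- m$provenance[, members, drop = FALSE]
    merged <- as.integer(rowSums(vals) > 0L)
    any_elic <- rowSums(prov == "elicited") > 0L
    j <- match(canonical_id(rep_labels[[k]]), names(out$feature_labels))
    rows <- which(merged == 1L)
    if (length(rows)) {
      out$values[rows, j] <- 1L
      out$provenance[rows, j] <- ifelse(any_elic[rows], "elicited", "imputed")
    }
  }
  validate_norm_matrix(out)
}

#' Subsample feature columns uniformly without replacement
#'
#' @param m a `norm_matrix`.
#' @param n number of features to keep (`n <= ncol`).
#' @param seed integer seed; the same seed reproduces the same sample.
#' @return a `norm_matrix` with `n` feature columns; concept rows unchanged.
#' @export
sample_features <- function(m, n, seed) {
  validate_norm_matrix(m)
  if (!is_count(n)) stopf("n must be a non-negative count")
  nf <- ncol(m$values)
  if (n > nf) stopf("cannot sample %d features from %d", n, nf)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  keep <- sort(sample.int(nf, n))
  ids <- names(m$feature_labels)[keep]
  new_norm_matrix(
    m$values[, keep, drop = FALSE],
    m$provenance[, keep, drop = FALSE],
    m$concept_labels,
    m$feature_labels[keep]
  )
}
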