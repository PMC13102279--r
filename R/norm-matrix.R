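# Binary concept-by-feature norm matrices with per-cell provenance.
#
# A norm matrix records, for every (concept, feature) cell, a binary value and
# where it came from: "elicited" (a participant produced the feature for the
# concept), "imputed" (a verifier cascade confirmed it), or "absent" (no
# evidence; the value is 0). The invariant value == 1 <=> provenance in
# {elicited, imputed} holds everywhere.

PROVENANCE_LEVELS <- c("absent", "elicited", "imputed")

#' Construct a binary concept-by-feature norm matrix
#'
#' Concepts and features are identified by case-folded, whitespace-trimmed
#' labels; the matrix stores rows and columns sorted by identifier so that a
#' given cell set always yields the same object regardless of input order.
#' Cells not listed in `cells` default to value 0 with provenance `"absent"`.
#'
#' @param concepts character vector of concept labels (rows). Distinct labels
#'   that collide after case-folding are an error.
#' @param features character vector of feature phrases (columns).
#' @param cells optional `data.frame` with columns `concept`, `feature`,
#'   `value` (0/1) and `provenance` (`"absent"`, `"elicited"`, `"imputed"`).
#'   A value of 1 requires provenance `"elicited"` or `"imputed"`; a value of
#'   0 requires `"absent"`.
#' @return an object of class `norm_matrix`.
#' @examples
#' m <- norm_matrix(
#'   concepts = c("dog", "alligator"),
#'   features = c("has ears", "has wheels"),
#'   cells = data.frame(
#'     concept = "dog", feature = "has ears",
#'     value = 1, provenance = "elicited"
#'   )
#' )
#' density_stats(m)
#' @export
norm_matrix <- function(concepts, features, cells = NULL) {
  concept_labels <- fold_label_set(concepts, "concept")
  feature_labels <- fold_label_set(features, "feature")
  nc <- length(concept_labels)
  nf <- length(feature_labels)
  values <- matrix(0L, nc, nf,
    dimnames = list(names(concept_labels), names(feature_labels))
  )
  prov <- matrix("absent", nc, nf,
    dimnames = list(names(concept_labels), names(feature_labels))
  )
  if (!is.null(cells) && nrow(cells) > 0L) {
    req <- c("concept", "feature", "value", "provenance")
    if (!all(req %in% names(cells))) {
      stopf("cells must have columns %s", paste(req, collapse = ", "))
    }
    ci <- canonical_id(cells$concept)
    fi <- canonical_id(cells$feature)
    unknown_c <- setdiff(ci, names(concept_labels))
    if (length(unknown_c)) stopf("unknown concept in cells: %s", unknown_c[1L])
    unknown_f <- setdiff(fi, names(feature_labels))
    if (length(unknown_f)) stopf("unknown feature in cells: %s", unknown_f[1L])
    key <- paste(ci, fi, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stopf("duplicate cell for (concept, feature) = (%s)", gsub("\r", ", ", d))
    }
    val <- as.integer(cells$value)
    pv <- as.character(cells$provenance)
    check_cell_consistency(val, pv)
    idx <- cbind(match(ci, names(concept_labels)), match(fi, names(feature_labels)))
    values[idx] <- val
    prov[idx] <- pv
  }
  new_norm_matrix(values, prov, concept_labels, feature_labels)
}

new_norm_matrix <- function(values, provenance, concept_labels, feature_labels) {
  structure(
    list(
      values = values,
      provenance = provenance,
      concept_labels = concept_labels,
      feature_labels = feature_labels
    ),
    class = "norm_matrix"
  )
}

check_cell_consistency <- function(value, provenance) {
  if (!all(value %in% c(0L, 1L))) {
    stopf("cell values must be 0 or 1")
  }
  if (!all(provenance %in% PROVENANCE_LEVELS)) {
    bad <- setdiff(unique(provenance), PROVENANCE_LEVELS)
    stopf("unknown provenance: %s", bad[1L])
  }
  mismatch <- (value == 1L) != (provenance %in% c("elicited", "imputed"))
  if (any(mismatch)) {
    stopf("cell invariant violated: value 1 requires provenance elicited/imputed, value 0 requires absent")
  }
  invisible(TRUE)
}

#' Validate a norm matrix object
#'
#' Checks the structural invariants: matching dimensions and dimnames, binary
#' values, known provenance codes, and value/provenance consistency.
#'
#' @param m a `norm_matrix`.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_norm_matrix <- function(m) {
  if (!inherits(m, "norm_matrix")) stopf("not a norm_matrix")
  if (!identical(dim(m$values), dim(m$provenance))) stopf("values/provenance dimension mismatch")
  chr0 <- function(x) if (is.null(x)) character() else x
  if (!identical(chr0(rownames(m$values)), chr0(names(m$concept_labels)))) stopf("concept ids out of sync")
  if (!identical(chr0(colnames(m$values)), chr0(names(m$feature_labels)))) stopf("feature ids out of sync")
  check_cell_consistency(as.vector(m$values), as.vector(m$provenance))
  invisible(m)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' Concepts of a norm matrix
#' @param m a `norm_matrix`.
#' @return `data.frame` with columns `id` and `label`, ordered by id.
#' @export
concepts <- function(m) {
  data.frame(id = names(m$concept_labels), label = unname(m$concept_labels))
}

#' Features of a norm matrix
#' @param m a `norm_matrix`.
#' @return `data.frame` with columns `id` and `phrase`, ordered by id.
#' @export
features <- function(m) {
  data.frame(id = names(m$feature_labels), phrase = unname(m$feature_labels))
}

#' @export
print.norm_matrix <- function(x, ...) {
  tab <- table(factor(x$provenance[x$values == 1L], levels = c("elicited", "imputed")))
  cat(sprintf(
    "norm_matrix: %d concepts x %d features, %d ones (%d elicited, %d imputed)\n",
    nrow(x$values), ncol(x$values), sum(x$values),
    tab[["elicited"]], tab[["imputed"]]
  ))
  invisible(x)
}

#' @export
summary.norm_matrix <- function(object, ...) {
  print(object)
  if (nrow(object$values) > 0L) print(density_stats(object))
  invisible(object)
}

#' @export
as.matrix.norm_matrix <- function(x, ...) x$values

#' Density diagnostics for a norm matrix
#'
#' Summarises how richly featured a matrix is: the mean number of true
#' features per concept (over all concepts, including those with none), the
#' mean number of concepts per feature, the fraction of *singleton* features
#' (true of exactly one concept, among features true of at least one), and
#' the total number of 1 cells. Human-elicited matrices are typically sparse
#' and singleton-heavy; verifier-imputed matrices are far denser with much
#' greater feature overlap between concepts.
#'
#' @param m a `norm_matrix` with at least one concept.
#' @return an object of class `density_stats`: a list with elements
#'   `mean_features_per_concept`, `mean_concepts_per_feature`,
#'   `singleton_feature_fraction` and `total_ones`.
#' @export
density_stats <- function(m) {
  validate_norm_matrix(m)
  if (nrow(m$values) == 0L) {
    stopf("density_stats undefined for a matrix with 0 concepts")
  }
  per_concept <- rowSums(m$values)
  per_feature <- colSums(m$values)
  nonzero <- per_feature[per_feature >= 1L]
  singleton <- if (length(nonzero)) sum(nonzero == 1L) / length(nonzero) else NaN
  structure(
    list(
      mean_features_per_concept = mean(per_concept),
      mean_concepts_per_feature = if (ncol(m$values) > 0L) mean(per_feature) else NaN,
      singleton_feature_fraction = singleton,
      total_ones = sum(m$values)
    ),
    class = "density_stats"
  )
}

#' @export
print.density_stats <- function(x, ...) {
  cat(sprintf(
    paste0(
      "density: %.2f features/concept, %.2f concepts/feature, ",
      "singleton fraction %.3f, %d ones\n"
    ),
    x$mean_features_per_concept, x$mean_concepts_per_feature,
    x$singleton_feature_fraction, x$total_ones
  ))
  invisible(x)
}

# Internal: set cells (matrix-index) to value/provenance, returning a new
# validated norm_matrix.
nm_set_cells <- function(m, idx, value, provenance) {
  if (nrow(idx) == 0L) return(m)
  m$values[idx] <- as.integer(value)
  m$provenance[idx] <- provenance
  validate_norm_matrix(m)
}
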