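# Shared internal helpers: identifier folding, deterministic hashing, misc checks.

#' Canonical identifier for a concept or feature label
#'
#' Identifiers are case-folded, whitespace-trimmed labels. All joins across
#' files (norm matrices, verdict tables, gold sets, triplet files) go through
#' this folding so that "Dog " and "dog" address the same row.
#'
#' @param x character vector of labels.
#' @return character vector of identifiers.
#' @export
canonical_id <- function(x) {
  tolower(trimws(as.character(x)))
}

# Validate a label set: non-empty after trimming, no two distinct labels that
# collide after folding. Returns labels named by their canonical ids, sorted
# by id.
fold_label_set <- function(labels, what = "label") {
  labels <- trimws(as.character(labels))
  if (any(!nzchar(labels))) {
    stop(sprintf("empty %s is not allowed", what), call. = FALSE)
  }
  ids <- canonical_id(labels)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf(
      "%s identifier collision after case-folding: %s",
      what, paste(utils::head(dup, 5L), collapse = ", ")
    ), call. = FALSE)
  }
  names(labels) <- ids
  labels[order(ids, method = "radix")]
}

# Deterministic 31-bit polynomial hash of a string, offset by an integer seed.
# Used to key per-pair random draws so simulated verdicts do not depend on
# query order. Processes three characters per step (h < 2^31 and 31^3 < 2^15,
# so intermediate values stay exactly representable in doubles).
string_hash31 <- function(seed, s) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed %% m)
  codes <- utf8ToInt(s)
  n <- length(codes)
  full <- n %/% 3L
  if (full > 0L) {
    for (k in seq_len(full)) {
      i <- 3L * (k - 1L)
      h <- (h * 29791 + codes[i + 1L] * 961 + codes[i + 2L] * 31 + codes[i + 3L]) %% m
    }
  }
  for (i in seq_len(n - 3L * full)) {
    h <- (h * 31 + codes[3L * full + i]) %% m
  }
  as.integer(h)
}

# One uniform draw keyed by (seed, key-string); independent of global RNG state
# and of the order in which pairs are queried.
keyed_uniform <- function(seed, key) {
  h <- string_hash31(seed, key)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(h)
  stats::runif(1L)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

is_probability <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
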