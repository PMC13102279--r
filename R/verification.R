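# Verifier machinery: prompt construction, response parsing, the two-stage
# reverification cascade, and full-matrix imputation.
#
# A verifier is anything satisfying the contract "prompt text in, raw
# response text out". The cascade queries a primary verifier for every pair
# and re-checks only its positive verdicts with a secondary verifier,
# retaining a 1 only when both agree — trading a little hit rate for a large
# reduction in false alarms.

PROMPT_TEMPLATE <- "In one word True or False, answer the following question:\nIs the property [%s] true for [%s]? Answer:"

#' Default two-shot exemplars
#'
#' One clearly true and one clearly false concept-feature pair used as
#' in-context examples for two-shot prompting. Configuration: any pair list
#' with exactly one true and one false exemplar may be substituted.
#' @export
default_exemplars <- function() {
  list(
    list(concept = "dog", feature = "has ears", truth = TRUE),
    list(concept = "alligator", feature = "has wheels", truth = FALSE)
  )
}

validate_exemplars <- function(exemplars) {
  if (!is.list(exemplars) || length(exemplars) != 2L) {
    stopf("exemplars must be a list of exactly two (concept, feature, truth) entries")
  }
  truths <- vapply(exemplars, function(e) isTRUE(e$truth), logical(1L))
  if (sum(truths) != 1L) stopf("exemplars must contain exactly one true and one false pair")
  # Present true-then-false regardless of input order.
  exemplars[order(!truths)]
}

#' Build a verification prompt
#'
#' Zero-shot text is exactly
#' `In one word True or False, answer the following question:` then
#' `Is the property [x] true for [y]? Answer:` with the feature `x` and
#' concept `y` substituted and the square brackets retained. Two-shot
#' prepends two exemplar question/answer blocks in the identical template
#' (true exemplar first, then false), the same exemplars for every prompt.
#'
#' @param feature the property phrase `x`.
#' @param concept the concept label `y`.
#' @param shots `"zero"` or `"two"`.
#' @param exemplars two-shot exemplars; see [default_exemplars()].
#' @return prompt text (single string).
#' @export
build_prompt <- function(feature, concept, shots = c("zero", "two"),
                         exemplars = default_exemplars()) {
  shots <- match.arg(shots)
  if (!is.character(feature) || length(feature) != 1L || !nzchar(trimws(feature))) {
    stopf("feature phrase must be a non-empty string")
  }
  if (!is.character(concept) || length(concept) != 1L || !nzchar(trimws(concept))) {
    stopf("concept label must be a non-empty string")
  }
  query <- sprintf(PROMPT_TEMPLATE, feature, concept)
  if (shots == "zero") {
    return(query)
  }
  exemplars <- validate_exemplars(exemplars)
  blocks <- vapply(exemplars, function(e) {
    paste0(
      sprintf(PROMPT_TEMPLATE, e$feature, e$concept),
      if (isTRUE(e$truth)) " True" else " False"
    )
  }, character(1L))
  paste(c(blocks, query), collapse = "\n\n")
}

# Recover the queried (feature, concept) pair from a prompt. Two-shot prompts
# contain three question blocks; the query is always the last line.
prompt_pair <- function(prompt) {
  nl <- gregexpr("\n", prompt, fixed = TRUE)[[1L]]
  last <- if (nl[1L] == -1L) prompt else substring(prompt, nl[length(nl)] + 1L)
  m <- regexec("Is the property \\[(.*)\\] true for \\[(.*)\\]\\? Answer:", last)[[1L]]
  if (m[1L] == -1L) stopf("prompt does not match the verification template")
  starts <- m[-1L]
  lens <- attr(m, "match.length")[-1L]
  list(
    feature = substring(last, starts[1L], starts[1L] + lens[1L] - 1L),
    concept = substring(last, starts[2L], starts[2L] + lens[2L] - 1L)
  )
}

#' Parse a raw verifier response into a boolean decision
#'
#' The response is truncated to its first five whitespace-delimited tokens,
#' scanned left to right. The first decisive token wins: a token containing
#' `"true"` or `"yes"` (case-insensitive substring) is positive; a token
#' containing `"false"`, or equal to `"no"` after stripping surrounding
#' punctuation (or starting with `"no"` followed by a non-letter), is
#' negative. `"no"` never fires inside words like "nothing" or "known". No
#' decisive token means negative. Total: every input yields a decision.
#'
#' @param raw response text.
#' @return `TRUE` or `FALSE`.
#' @export
parse_response <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) return(FALSE)
  tokens <- strsplit(trimws(tolower(raw)), "\\s+")[[1L]]
  tokens <- utils::head(tokens[nzchar(tokens)], 5L)
  for (tok in tokens) {
    if (grepl("true", tok, fixed = TRUE) || grepl("yes", tok, fixed = TRUE)) {
      return(TRUE)
    }
    if (grepl("false", tok, fixed = TRUE)) {
      return(FALSE)
    }
    core <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", tok)
    if (core == "no" || grepl("^no[^a-z]", core)) {
      return(FALSE)
    }
  }
  FALSE
}

#' Define a verifier
#'
#' @param name identifier used in verdict audit trails.
#' @param respond function taking a prompt string and returning raw response
#'   text (possibly empty). Must be total; exceptions it raises are caught by
#'   the cascade and recorded as failures.
#' @return object of class `verifier`.
#' @export
verifier <- function(name, respond) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) stopf("verifier name required")
  if (!is.function(respond)) stopf("respond must be a function(prompt) -> text")
  structure(list(name = name, respond = respond), class = "verifier")
}

#' @export
print.verifier <- function(x, ...) {
  cat(sprintf("verifier: %s\n", x$name))
  invisible(x)
}

# Deterministic pair ordering shared by all batch operations: concept id,
# then feature id.
order_pairs <- function(pairs) {
  ci <- canonical_id(pairs$concept)
  fi <- canonical_id(pairs$feature)
  ord <- order(ci, fi, method = "radix")
  pairs[ord, , drop = FALSE]
}

# Vectorized prompt construction for batch operations (same text as
# build_prompt, validated once per batch).
build_prompts <- function(features, concepts, shots, exemplars) {
  if (any(!nzchar(trimws(features)))) stopf("feature phrase must be a non-empty string")
  if (any(!nzchar(trimws(concepts)))) stopf("concept label must be a non-empty string")
  q <- sprintf(PROMPT_TEMPLATE, features, concepts)
  if (shots == "two") {
    exemplars <- validate_exemplars(exemplars)
    prefix <- paste(vapply(exemplars, function(e) {
      paste0(
        sprintf(PROMPT_TEMPLATE, e$feature, e$concept),
        if (isTRUE(e$truth)) " True" else " False"
      )
    }, character(1L)), collapse = "\n\n")
    q <- paste0(prefix, "\n\n", q)
  }
  q
}

query_one <- function(v, prompt) {
  tryCatch(
    list(raw = as.character(v$respond(prompt))[1L], failed = FALSE),
    error = function(e) list(raw = NA_character_, failed = TRUE)
  )
}

#' Query a single verifier over a batch of pairs
#'
#' @param pairs `data.frame` with columns `concept`, `feature`.
#' @param v a [verifier()].
#' @param shots `"zero"` or `"two"`.
#' @param exemplars see [build_prompt()].
#' @return a `verdict_table` data frame with columns `concept`, `feature`,
#'   `model`, `shots`, `raw_response`, `decision`, `failed`. Failed queries
#'   carry decision `FALSE` and `failed = TRUE`; the failure count is in
#'   `attr(, "n_failures")`.
#' @export
verify_pairs <- function(pairs, v, shots = c("zero", "two"),
                         exemplars = default_exemplars()) {
  shots <- match.arg(shots)
  pairs <- order_pairs(pairs)
  n <- nrow(pairs)
  prompts <- build_prompts(pairs$feature, pairs$concept, shots, exemplars)
  raw <- character(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    ans <- query_one(v, prompts[i])
    raw[i] <- ans$raw
    failed[i] <- ans$failed
  }
  decision <- vapply(raw, parse_response, logical(1L), USE.NAMES = FALSE)
  decision[failed] <- FALSE
  out <- data.frame(
    concept = pairs$concept, feature = pairs$feature,
    model = v$name, shots = shots,
    raw_response = raw, decision = decision, failed = failed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("verdict_table", "data.frame")
  attr(out, "n_failures") <- sum(failed)
  out
}

#' Two-stage reverification cascade
#'
#' Queries the primary verifier for every pair; pairs it judges positive are
#' re-checked by the secondary verifier, and the final decision is the
#' logical AND of the two (a primary negative is final, and the secondary is
#' never consulted for it). Verifier exceptions mark the pair failed
#' (decision `FALSE`) and the run continues.
#'
#' @param pairs `data.frame` with columns `concept`, `feature`.
#' @param primary,secondary [verifier()] objects.
#' @param shots `"zero"` or `"two"`.
#' @param exemplars see [build_prompt()].
#' @return a `verdict_table` data frame (columns `concept`, `feature`,
#'   `model`, `shots`, `raw_primary`, `decision_primary`, `raw_secondary`,
#'   `decision_secondary`, `decision`, `failed`) in deterministic (concept
#'   id, feature id) order, with attributes `n_secondary_queries` (equals the
#'   primary positive count among non-failed pairs) and `n_failures`.
#' @export
cascade_verify <- function(pairs, primary, secondary, shots = c("zero", "two"),
                           exemplars = default_exemplars()) {
  shots <- match.arg(shots)
  pairs <- order_pairs(pairs)
  n <- nrow(pairs)
  prompts <- build_prompts(pairs$feature, pairs$concept, shots, exemplars)
  raw1 <- character(n)
  raw2 <- rep(NA_character_, n)
  d1 <- logical(n)
  d2 <- rep(NA, n)
  failed <- logical(n)
  n_secondary <- 0L
  for (i in seq_len(n)) {
    pr <- prompts[i]
    a1 <- query_one(primary, pr)
    raw1[i] <- a1$raw
    if (a1$failed) {
      failed[i] <- TRUE
      next
    }
    d1[i] <- parse_response(a1$raw)
    if (d1[i]) {
      a2 <- query_one(secondary, pr)
      raw2[i] <- a2$raw
      if (a2$failed) {
        failed[i] <- TRUE
        next
      }
      n_secondary <- n_secondary + 1L
      d2[i] <- parse_response(a2$raw)
    }
  }
  decision <- !failed & d1 & !is.na(d2) & d2
  decision[is.na(decision)] <- FALSE
  out <- data.frame(
    concept = pairs$concept, feature = pairs$feature,
    model = paste0(primary$name, "+", secondary$name), shots = shots,
    raw_primary = raw1, decision_primary = d1,
    raw_secondary = raw2, decision_secondary = d2,
    decision = decision, failed = failed,
    stringsAsFactors = FALSE
  )
  class(out) <- c("verdict_table", "data.frame")
  attr(out, "n_secondary_queries") <- n_secondary
  attr(out, "n_failures") <- sum(failed)
  out
}

#' @export
print.verdict_table <- function(x, ...) {
  cat(sprintf(
    "verdict_table: %d pairs, %d positive, %d failed (%s)\n",
    nrow(x), sum(x$decision), attr(x, "n_failures") %||% sum(x$failed),
    paste(unique(x$model), collapse = ", ")
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Impute the zero cells of a norm matrix through a verifier cascade
#'
#' Every 1 cell is left untouched and never queried. Every 0 cell is routed
#' through [cascade_verify()]; cascade-positive cells become 1 with
#' provenance `"imputed"`, all others stay 0/absent.
#'
#' @param human a `norm_matrix` of elicited data.
#' @param primary,secondary [verifier()] objects.
#' @param shots `"zero"` or `"two"`.
#' @param exemplars see [build_prompt()].
#' @return the imputed `norm_matrix`, with an `imputation_summary` attribute
#'   (list: `n_queried`, `n_positive`, `n_failures`) and the full cascade
#'   `verdict_table` in attribute `verdicts`.
#' @export
impute_matrix <- function(human, primary, secondary, shots = c("zero", "two"),
                          exemplars = default_exemplars()) {
  shots <- match.arg(shots)
  validate_norm_matrix(human)
  zero <- which(human$values == 0L, arr.ind = TRUE)
  if (nrow(zero) == 0L) {
    attr(human, "imputation_summary") <- list(n_queried = 0L, n_positive = 0L, n_failures = 0L)
    return(human)
  }
  pairs <- data.frame(
    concept = unname(human$concept_labels[zero[, 1L]]),
    feature = unname(human$feature_labels[zero[, 2L]]),
    stringsAsFactors = FALSE
  )
  vt <- cascade_verify(pairs, primary, secondary, shots, exemplars)
  pos <- vt[vt$decision, , drop = FALSE]
  out <- human
  if (nrow(pos) > 0L) {
    idx <- cbind(
      match(canonical_id(pos$concept), names(human$concept_labels)),
      match(canonical_id(pos$feature), names(human$feature_labels))
    )
    out <- nm_set_cells(out, idx, 1L, "imputed")
  }
  attr(out, "imputation_summary") <- list(
    n_queried = nrow(pairs),
    n_positive = nrow(pos),
    n_failures = attr(vt, "n_failures")
  )
  attr(out, "verdicts") <- vt
  out
}

#' Write / read a verdict table as JSONL
#'
#' One record per stage per pair with fields `concept`, `feature`, `model`,
#' `shots`, `raw_response`, `decision` and `stage` in `primary`, `secondary`,
#' `final` (single-stage tables write `final` records only).
#'
#' @param vt a `verdict_table`.
#' @param path file path.
#' @export
write_verdicts <- function(vt, path) {
  recs <- list()
  cascade <- "raw_primary" %in% names(vt)
  for (i in seq_len(nrow(vt))) {
    if (cascade) {
      recs[[length(recs) + 1L]] <- list(
        concept = vt$concept[i], feature = vt$feature[i], model = vt$model[i],
        shots = vt$shots[i], raw_response = vt$raw_primary[i],
        decision = vt$decision_primary[i], stage = "primary"
      )
      if (!is.na(vt$raw_secondary[i])) {
        recs[[length(recs) + 1L]] <- list(
          concept = vt$concept[i], feature = vt$feature[i], model = vt$model[i],
          shots = vt$shots[i], raw_response = vt$raw_secondary[i],
          decision = vt$decision_secondary[i], stage = "secondary"
        )
      }
      raw_final <- if (is.na(vt$raw_secondary[i])) vt$raw_primary[i] else vt$raw_secondary[i]
    } else {
      raw_final <- vt$raw_response[i]
    }
    recs[[length(recs) + 1L]] <- list(
      concept = vt$concept[i], feature = vt$feature[i], model = vt$model[i],
      shots = vt$shots[i], raw_response = raw_final,
      decision = vt$decision[i], stage = "final"
    )
  }
  write_jsonl(recs, path)
}

#' @rdname write_verdicts
#' @export
read_verdicts <- function(path) {
  recs <- read_jsonl(path)
  recs <- Filter(function(r) identical(r$stage, "final"), recs)
  out <- data.frame(
    concept = vapply(recs, function(r) as.character(r$concept), character(1L)),
    feature = vapply(recs, function(r) as.character(r$feature), character(1L)),
    model = vapply(recs, function(r) as.character(r$model), character(1L)),
    shots = vapply(recs, function(r) as.character(r$shots), character(1L)),
    raw_response = vapply(recs, function(r) {
      if (is.null(r$raw_response)) NA_character_ else as.character(r$raw_response)
    }, character(1L)),
    decision = vapply(recs, function(r) isTRUE(r$decision), logical(1L)),
    failed = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("verdict_table", "data.frame")
  attr(out, "n_failures") <- 0L
  out
}
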