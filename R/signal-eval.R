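# Signal-detection evaluation of verification strategies against unanimous
# human judgments: gold-set construction, confusion counts, d-prime with the
# half-count clamp for extreme rates, percentile bootstrap CIs over pairs,
# and strategy comparison reports.

new_gold_set <- function(df) {
  class(df) <- c("gold_set", "data.frame")
  df
}

#' Build a gold set of unanimous judgments
#'
#' Skip responses are discarded first; a pair enters the gold set when it has
#' at least `min_raters` remaining judgments and they are unanimous (all true
#' or all false). Pairs with any disagreement, or too few usable judgments,
#' are excluded.
#'
#' @param judgments `data.frame` with columns `concept`, `feature`, `rater`,
#'   `response` (`"true"`, `"false"`, `"skip"`).
#' @param min_raters minimum non-skip judgments per pair (default 5).
#' @return a `gold_set` data frame with columns `concept`, `feature`,
#'   `label` (logical) and `n` (judgment count), ordered by concept then
#'   feature id.
#' @export
build_gold_set <- function(judgments, min_raters = 5L) {
  if (!is_count(min_raters) || min_raters < 1L) stopf("min_raters must be >= 1")
  keep <- judgments$response %in% c("true", "false")
  j <- judgments[keep, , drop = FALSE]
  if (nrow(j) == 0L) {
    return(new_gold_set(data.frame(
      concept = character(), feature = character(),
      label = logical(), n = integer(), stringsAsFactors = FALSE
    )))
  }
  key <- paste(canonical_id(j$concept), canonical_id(j$feature), sep = "\r")
  groups <- split(seq_len(nrow(j)), key)
  rows <- lapply(groups, function(idx) {
    resp <- j$response[idx]
    if (length(resp) < min_raters) return(NULL)
    if (length(unique(resp)) != 1L) return(NULL)
    data.frame(
      concept = j$concept[idx[1L]], feature = j$feature[idx[1L]],
      label = resp[1L] == "true", n = length(resp), stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(new_gold_set(data.frame(
      concept = character(), feature = character(),
      label = logical(), n = integer(), stringsAsFactors = FALSE
    )))
  }
  out <- do.call(rbind, rows)
  ord <- order(canonical_id(out$concept), canonical_id(out$feature), method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  new_gold_set(out)
}

#' @export
print.gold_set <- function(x, ...) {
  cat(sprintf(
    "gold_set: %d pairs (%d true, %d false)\n",
    nrow(x), sum(x$label), sum(!x$label)
  ))
  invisible(x)
}

# Join gold pairs to verdict decisions; error listing missing pairs.
gold_decisions <- function(gold, verdicts) {
  gk <- paste(canonical_id(gold$concept), canonical_id(gold$feature), sep = "\r")
  vk <- paste(canonical_id(verdicts$concept), canonical_id(verdicts$feature), sep = "\r")
  idx <- match(gk, vk)
  if (anyNA(idx)) {
    missing <- gold[is.na(idx), c("concept", "feature"), drop = FALSE]
    stopf(
      "verdicts do not cover %d gold pair(s), e.g.: %s",
      nrow(missing),
      paste(utils::head(paste(missing$concept, missing$feature, sep = "/"), 3L), collapse = "; ")
    )
  }
  data.frame(label = gold$label, decision = verdicts$decision[idx])
}

#' Confusion counts of a verdict table against a gold set
#'
#' Human unanimous labels are the signal, verifier decisions the guesses:
#' gold-true pairs score as hits (verdict true) or misses; gold-false pairs
#' as false alarms (verdict true) or correct rejections.
#'
#' @param gold a [build_gold_set()] result.
#' @param verdicts a `verdict_table` covering every gold pair.
#' @return object of class `confusion_counts`: list with `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`.
#' @export
confusion_counts <- function(gold, verdicts) {
  gd <- gold_decisions(gold, verdicts)
  structure(
    list(
      hits = sum(gd$label & gd$decision),
      misses = sum(gd$label & !gd$decision),
      false_alarms = sum(!gd$label & gd$decision),
      correct_rejections = sum(!gd$label & !gd$decision)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "confusion: %d hits, %d misses, %d false alarms, %d correct rejections\n",
    x$hits, x$misses, x$false_alarms, x$correct_rejections
  ))
  invisible(x)
}

clamp_rate <- function(k, n) {
  lo <- 1 / (2 * n)
  min(max(k / n, lo), 1 - lo)
}

#' Signal-detection d-prime from confusion counts
#'
#' `d' = z(H) - z(F)` with `z` the inverse standard-normal CDF, `H` the hit
#' rate and `F` the false-alarm rate. Perfect or zero rates are clamped into
#' `[1/(2N), 1 - 1/(2N)]` for each rate's own `N` (the half-count
#' convention) so the z-transform stays finite.
#'
#' @param counts a [confusion_counts()] object (or compatible list).
#' @param correction extreme-rate correction; only `"clamp-half-count"` is
#'   implemented.
#' @return object of class `dprime_result`: list with `H`, `F`, `dprime`,
#'   `ci` (`NULL` until [bootstrap_ci()] fills it) and the input `counts`.
#' @export
dprime <- function(counts, correction = "clamp-half-count") {
  correction <- match.arg(correction, "clamp-half-count")
  npos <- counts$hits + counts$misses
  nneg <- counts$false_alarms + counts$correct_rejections
  if (npos < 1L || nneg < 1L) {
    stopf("d-prime undefined: need at least one gold-true and one gold-false pair")
  }
  H <- clamp_rate(counts$hits, npos)
  F <- clamp_rate(counts$false_alarms, nneg)
  structure(
    list(
      H = H, F = F,
      dprime = stats::qnorm(H) - stats::qnorm(F),
      ci = NULL, counts = counts
    ),
    class = "dprime_result"
  )
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.4f (H = %.4f, F = %.4f)", x$dprime, x$H, x$F))
  if (!is.null(x$ci)) {
    cat(sprintf(", %g%% CI [%.4f, %.4f]", 100 * x$ci$level, x$ci$low, x$ci$high))
  }
  cat("\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for d-prime
#'
#' Resamples gold pairs (the unit of analysis) with replacement `n_boot`
#' times, recomputes d-prime on each replicate, and returns the percentile
#' interval. Replicates in which a resample contains no gold-true or no
#' gold-false pairs are recorded as missing; more than 10% missing
#' replicates aborts with an instability error.
#'
#' @param gold a gold set.
#' @param verdicts a `verdict_table` covering it.
#' @param n_boot number of replicates (>= 100; default 1000).
#' @param level interval level in (0, 1) (default 0.95).
#' @param seed integer seed; same seed, same interval.
#' @return list with `low`, `high`, `level`, `n_boot`, `n_missing` and the
#'   point estimate `dprime`.
#' @export
bootstrap_ci <- function(gold, verdicts, n_boot = 1000L, level = 0.95, seed = 1L) {
  if (!is_count(n_boot) || n_boot < 100L) stopf("n_boot must be >= 100")
  if (!is.numeric(level) || level <= 0 || level >= 1) stopf("level must be in (0, 1)")
  gd <- gold_decisions(gold, verdicts)
  n <- nrow(gd)
  if (n == 0L) stopf("empty gold set")
  # Outcome codes: 1 hit, 2 miss, 3 false alarm, 4 correct rejection.
  code <- ifelse(gd$label, ifelse(gd$decision, 1L, 2L), ifelse(gd$decision, 3L, 4L))
  point <- dprime(confusion_counts(gold, verdicts))$dprime
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  # Clamp bounds come from the full gold set's class sizes (a fixed smoothing
  # constant of the dataset), so replicates of a homogeneous gold set are
  # exactly constant.
  npos0 <- sum(gd$label)
  nneg0 <- n - npos0
  lo_pos <- 1 / (2 * npos0)
  lo_neg <- 1 / (2 * nneg0)
  ds <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    tab <- tabulate(code[sample.int(n, n, replace = TRUE)], nbins = 4L)
    npos <- tab[1L] + tab[2L]
    nneg <- tab[3L] + tab[4L]
    if (npos == 0L || nneg == 0L) next
    H <- min(max(tab[1L] / npos, lo_pos), 1 - lo_pos)
    F <- min(max(tab[3L] / nneg, lo_neg), 1 - lo_neg)
    ds[b] <- stats::qnorm(H) - stats::qnorm(F)
  }
  n_missing <- sum(is.na(ds))
  if (n_missing > 0.1 * n_boot) {
    stopf("bootstrap unstable: %d of %d replicates had an empty class", n_missing, n_boot)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(ds[!is.na(ds)], c(alpha, 1 - alpha), names = FALSE)
  list(
    low = q[1L], high = q[2L], level = level,
    n_boot = n_boot, n_missing = n_missing, dprime = point
  )
}

#' Compare verification strategies on one gold set
#'
#' Computes a `dprime_result` per strategy (optionally with bootstrap CIs)
#' and returns them ranked by descending d-prime, deterministic ties broken
#' by strategy name.
#'
#' @param gold a gold set.
#' @param tables named list of `verdict_table`s, each covering the gold set.
#' @param n_boot optional bootstrap replicate count; `NULL` skips CIs.
#' @param level CI level.
#' @param seed bootstrap seed.
#' @return a `strategy_ranking` data frame with one row per strategy:
#'   `strategy`, the four confusion counts, `H`, `F`, `dprime`, `ci_low`,
#'   `ci_high`.
#' @export
compare_strategies <- function(gold, tables, n_boot = NULL, level = 0.95, seed = 1L) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stopf("tables must be a named list")
  }
  rows <- lapply(names(tables), function(nm) {
    cc <- confusion_counts(gold, tables[[nm]])
    dp <- dprime(cc)
    ci_low <- NA_real_
    ci_high <- NA_real_
    if (!is.null(n_boot)) {
      ci <- bootstrap_ci(gold, tables[[nm]], n_boot = n_boot, level = level, seed = seed)
      ci_low <- ci$low
      ci_high <- ci$high
    }
    data.frame(
      strategy = nm, hits = cc$hits, misses = cc$misses,
      false_alarms = cc$false_alarms, correct_rejections = cc$correct_rejections,
      H = dp$H, F = dp$F, dprime = dp$dprime,
      ci_low = ci_low, ci_high = ci_high, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$dprime, out$strategy, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("strategy_ranking", "data.frame")
  out
}

#' @export
print.strategy_ranking <- function(x, ...) {
  cat("strategy ranking by d':\n")
  for (i in seq_len(nrow(x))) {
    ci <- if (!is.na(x$ci_low[i])) sprintf(" CI [%.3f, %.3f]", x$ci_low[i], x$ci_high[i]) else ""
    cat(sprintf(
      "  %d. %s  d' = %.4f (H = %.3f, F = %.3f)%s\n",
      i, x$strategy[i], x$dprime[i], x$H[i], x$F[i], ci
    ))
  }
  invisible(x)
}
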