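# Readers and writers for the on-disk interchange formats.
#
# Canonical norm-matrix format is long TSV with an explicit provenance column
# (concept<TAB>feature<TAB>value<TAB>provenance); dense CSV is an interchange
# convenience that loses provenance (all 1s read back as elicited). All files
# are UTF-8 with LF line endings; writers are deterministic (rows ordered by
# concept id then feature id) so identical matrices produce byte-identical
# files.

LONG_TSV_HEADER <- "concept\tfeature\tvalue\tprovenance"

#' Read a norm matrix from disk
#'
#' @param path file path.
#' @param dialect `"long-tsv"` (canonical, with provenance) or `"dense-csv"`
#'   (concepts as rows, features as columns, cells in 0/1; 1s read back with
#'   provenance `"elicited"`).
#' @return a [norm_matrix()].
#' @export
read_norm_matrix <- function(path, dialect = c("long-tsv", "dense-csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "long-tsv") read_norm_long_tsv(path) else read_norm_dense_csv(path)
}

read_norm_long_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || lines[1L] != LONG_TSV_HEADER) {
    stopf("parse error at line 1: expected header %s", gsub("\t", "\\\\t", LONG_TSV_HEADER))
  }
  body <- lines[-1L]
  body_line <- seq_along(body) + 1L
  keep <- nzchar(body)
  body <- body[keep]
  body_line <- body_line[keep]
  if (length(body) == 0L) {
    return(norm_matrix(character(), character()))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4L)) {
    bad <- body_line[which(nfield != 4L)[1L]]
    stopf("parse error at line %d: expected 4 tab-separated fields", bad)
  }
  rec <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  concept <- rec[, 1L]
  feature <- rec[, 2L]
  value <- rec[, 3L]
  prov <- rec[, 4L]
  bad_val <- !(value %in% c("0", "1"))
  if (any(bad_val)) {
    stopf("parse error at line %d: value must be 0 or 1", body_line[which(bad_val)[1L]])
  }
  bad_prov <- !(prov %in% PROVENANCE_LEVELS)
  if (any(bad_prov)) {
    stopf("parse error at line %d: unknown provenance", body_line[which(bad_prov)[1L]])
  }
  val <- as.integer(value)
  inconsistent <- (val == 1L) != (prov %in% c("elicited", "imputed"))
  if (any(inconsistent)) {
    stopf(
      "parse error at line %d: value/provenance inconsistent",
      body_line[which(inconsistent)[1L]]
    )
  }
  cid <- canonical_id(concept)
  fid <- canonical_id(feature)
  check_label_consistency(concept, cid, "concept")
  check_label_consistency(feature, fid, "feature")
  key <- paste(cid, fid, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stopf(
      "duplicate cell at line %d: (%s, %s)",
      body_line[d], concept[d], feature[d]
    )
  }
  # Default 0/absent cells may be omitted from the file; only non-default
  # cells need storing.
  keep_cells <- val == 1L
  norm_matrix(
    concepts = unique(concept),
    features = unique(feature),
    cells = data.frame(
      concept = concept[keep_cells], feature = feature[keep_cells],
      value = val[keep_cells], provenance = prov[keep_cells],
      stringsAsFactors = FALSE
    )
  )
}

# Two distinct raw labels folding to the same id within one file is a
# collision error (deterministic joins depend on the folding being invertible
# within a file).
check_label_consistency <- function(labels, ids, what) {
  first <- tapply(labels, ids, function(x) x[1L])
  bad <- labels != first[ids]
  if (any(bad)) {
    i <- which(bad)[1L]
    stopf(
      "%s label collision after case-folding: %s vs %s",
      what, labels[i], first[[ids[i]]]
    )
  }
  invisible(TRUE)
}

read_norm_dense_csv <- function(path) {
  df <- utils::read.csv(path,
    check.names = FALSE, stringsAsFactors = FALSE,
    fileEncoding = "UTF-8"
  )
  if (ncol(df) < 1L) stopf("parse error: dense-csv needs a concept column")
  feats <- colnames(df)[-1L]
  conc <- as.character(df[[1L]])
  if (length(feats) == 0L && length(conc) == 0L) {
    return(norm_matrix(character(), character()))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "integer"
  if (anyNA(vals) || !all(vals %in% c(0L, 1L))) {
    stopf("parse error: dense-csv cells must be 0 or 1")
  }
  ones <- which(vals == 1L, arr.ind = TRUE)
  norm_matrix(
    concepts = conc,
    features = feats,
    cells = data.frame(
      concept = conc[ones[, 1L]], feature = feats[ones[, 2L]],
      value = 1L, provenance = "elicited",
      stringsAsFactors = FALSE
    )
  )
}

#' Write a norm matrix to disk
#'
#' Long TSV emits one row per cell (every concept-feature combination, so the
#' matrix shape survives the round trip), ordered by concept id then feature
#' id; `read_norm_matrix(write_norm_matrix(m, p), )` reproduces `m` exactly
#' and repeated writes are byte-identical.
#'
#' @param m a `norm_matrix`.
#' @param path output path.
#' @param dialect `"long-tsv"` or `"dense-csv"`.
#' @return `path`, invisibly.
#' @export
write_norm_matrix <- function(m, path, dialect = c("long-tsv", "dense-csv")) {
  dialect <- match.arg(dialect)
  validate_norm_matrix(m)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (dialect == "long-tsv") {
    nc <- nrow(m$values)
    nf <- ncol(m$values)
    lines <- LONG_TSV_HEADER
    if (nc > 0L && nf > 0L) {
      rows <- sprintf(
        "%s\t%s\t%d\t%s",
        rep(unname(m$concept_labels), each = nf),
        rep(unname(m$feature_labels), times = nc),
        as.integer(t(m$values)),
        as.character(t(m$provenance))
      )
      lines <- c(lines, rows)
    }
    writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  } else {
    header <- paste(c("concept", csv_quote(unname(m$feature_labels))), collapse = ",")
    rows <- character(nrow(m$values))
    for (i in seq_len(nrow(m$values))) {
      rows[i] <- paste(
        c(csv_quote(m$concept_labels[[i]]), as.integer(m$values[i, ])),
        collapse = ","
      )
    }
    writeLines(enc2utf8(c(header, rows)), con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

csv_quote <- function(x) {
  needs <- grepl("[,\"\n]", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

# ---------------------------------------------------------------------------
# JSONL helpers

write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(
    records,
    function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")),
    character(1L)
  )
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON)
}

#' Read rater judgment records from JSONL
#'
#' One JSON object per line with fields `concept`, `feature`, `rater`, and
#' `response` in `"true"`, `"false"`, `"skip"`.
#'
#' @param path file path.
#' @return `data.frame` with those four columns.
#' @export
read_judgments <- function(path) {
  recs <- read_jsonl(path)
  if (length(recs) == 0L) {
    return(data.frame(
      concept = character(), feature = character(),
      rater = character(), response = character()
    ))
  }
  out <- data.frame(
    concept = vapply(recs, function(r) as.character(r$concept), character(1L)),
    feature = vapply(recs, function(r) as.character(r$feature), character(1L)),
    rater = vapply(recs, function(r) as.character(r$rater), character(1L)),
    response = vapply(recs, function(r) as.character(r$response), character(1L)),
    stringsAsFactors = FALSE
  )
  bad <- !(out$response %in% c("true", "false", "skip"))
  if (any(bad)) stopf("judgment response must be true/false/skip (line %d)", which(bad)[1L])
  out
}

#' Write rater judgment records to JSONL
#' @param judgments `data.frame` with columns `concept`, `feature`, `rater`,
#'   `response`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_judgments <- function(judgments, path) {
  recs <- lapply(seq_len(nrow(judgments)), function(i) {
    list(
      concept = judgments$concept[i], feature = judgments$feature[i],
      rater = judgments$rater[i], response = judgments$response[i]
    )
  })
  write_jsonl(recs, path)
}

#' Read a gold set from TSV
#'
#' Columns `concept`, `feature`, `label` (`true`/`false`), `n` (judgment
#' count).
#' @param path file path.
#' @return a `gold_set` data frame (see [build_gold_set()]).
#' @export
read_gold_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("concept", "feature", "label", "n")
  if (!all(req %in% names(df))) stopf("gold set needs columns %s", paste(req, collapse = ", "))
  new_gold_set(data.frame(
    concept = as.character(df$concept), feature = as.character(df$feature),
    label = as.character(df$label) == "true", n = as.integer(df$n),
    stringsAsFactors = FALSE
  ))
}

#' Write a gold set to TSV
#' @param gold a `gold_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gold_set <- function(gold, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(
    "concept\tfeature\tlabel\tn",
    sprintf(
      "%s\t%s\t%s\t%d", gold$concept, gold$feature,
      ifelse(gold$label, "true", "false"), gold$n
    )
  )
  writeLines(enc2utf8(lines), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
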