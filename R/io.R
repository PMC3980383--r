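# Flat-file readers and writers. Everything is tab-delimited text; identifiers
# are opaque strings and node order is first-appearance order throughout.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) dp_stop(sprintf("file not found: %s", path), "drugprop_io_error")
  readLines(path, warn = FALSE)
}

#' Read a network edge list
#'
#' Reads a tab-delimited edge list with 2 or 3 columns (`from`, `to`,
#' optional `weight`; missing weights default to 1). For undirected input,
#' duplicate pairs (in either orientation) are collapsed keeping the maximum
#' weight -- similarity semantics, not multiplicity. Self-loops are dropped
#' with a logged count.
#'
#' @param path Path to the edge-list file.
#' @param directed If `FALSE` (default), `(a, b)` and `(b, a)` are the same
#'   edge.
#'
#' @return A data frame with columns `from`, `to`, `weight`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- read_tsv_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) dp_validation_error(sprintf("empty edge list: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  bad <- which(n_col < 2 | n_col > 3)
  if (length(bad)) {
    dp_parse_error(sprintf("malformed row at line %d of %s (expected 2 or 3 columns)",
                           line_no[bad[1]], path))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  weight <- rep(1.0, length(parts))
  has_w <- n_col == 3L
  if (any(has_w)) {
    w_raw <- vapply(parts[has_w], `[[`, "", 3L)
    w <- suppressWarnings(as.numeric(w_raw))
    if (anyNA(w)) {
      dp_parse_error(sprintf("non-numeric weight at line %d of %s",
                             line_no[has_w][which(is.na(w))[1]], path))
    }
    weight[has_w] <- w
  }
  if (any(weight < 0)) {
    dp_validation_error(sprintf("negative weight at line %d of %s",
                                line_no[which(weight < 0)[1]], path))
  }
  loops <- from == to
  if (any(loops)) {
    dp_log("dropped %d self-loop(s) from %s", sum(loops), path)
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  if (!length(from)) dp_validation_error(sprintf("no usable edges in %s", path))
  key <- if (directed) paste(from, to, sep = "\r") else {
    paste(pmin(from, to), pmax(from, to), sep = "\r")
  }
  first <- !duplicated(key)
  w_max <- tapply(weight, key, max)
  out <- data.frame(from = from[first], to = to[first],
                    weight = as.numeric(w_max[key[first]]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a network edge list
#'
#' Inverse of [read_edge_list()]: writes `from\tto\tweight` rows with
#' deterministic number formatting.
#'
#' @param path Output path.
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @export
write_edge_list <- function(path, edges) {
  lines <- sprintf("%s\t%s\t%s", edges$from, edges$to, format_num(edges$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Read a case/control expression matrix
#'
#' The matrix file has a header `gene_id<TAB>sample...`; the labels file maps
#' each sample name to `case` or `control` (two tab-separated columns). Genes
#' with any missing value are dropped with a logged count (no imputation).
#'
#' @param path Path to the expression matrix TSV.
#' @param labels_path Path to the sample-label TSV.
#'
#' @return An [expression_profile()] with samples in header order.
#' @export
read_expression_matrix <- function(path, labels_path) {
  mat <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2) dp_validation_error(sprintf("expression matrix %s has no sample columns", path))
  genes <- as.character(mat[[1]])
  values <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  samples <- colnames(values)
  lab_df <- utils::read.delim(labels_path, header = FALSE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (ncol(lab_df) < 2) dp_validation_error(sprintf("label file %s needs two columns", labels_path))
  labels <- stats::setNames(tolower(as.character(lab_df[[2]])), as.character(lab_df[[1]]))
  missing <- setdiff(samples, names(labels))
  if (length(missing)) {
    dp_validation_error(sprintf("sample(s) missing from label file: %s",
                                paste(missing, collapse = ", ")))
  }
  sample_labels <- unname(labels[samples])
  incomplete <- rowSums(is.na(values)) > 0
  if (any(incomplete)) {
    dp_log("dropped %d gene(s) with missing expression values", sum(incomplete))
    genes <- genes[!incomplete]
    values <- values[!incomplete, , drop = FALSE]
  }
  expression_profile(genes, values, sample_labels)
}

#' Write an expression profile to matrix + label files
#'
#' @param profile An [expression_profile()].
#' @param path,labels_path Output paths for matrix and labels.
#' @export
write_expression_matrix <- function(profile, path, labels_path) {
  samples <- sprintf("S%d", seq_along(profile$sample_labels))
  header <- paste(c("gene_id", samples), collapse = "\t")
  body <- vapply(seq_along(profile$gene_ids), function(i) {
    paste(c(profile$gene_ids[i], format_num(profile$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  writeLines(sprintf("%s\t%s", samples, profile$sample_labels), labels_path)
  invisible(path)
}

#' Read a two-column association pair list
#'
#' Duplicated pairs are dropped; order of first appearance is preserved.
#'
#' @param path Path to a 2-column tab-delimited file.
#'
#' @return A data frame with columns `from`, `to`.
#' @export
read_association_pairs <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) dp_validation_error(sprintf("empty association file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    dp_parse_error(sprintf("malformed pair at line %d of %s",
                           which(lengths(parts) < 2)[1], path))
  }
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' Write an association pair list
#'
#' @param path Output path.
#' @param pairs Data frame with columns `from`, `to`.
#' @export
write_association_pairs <- function(path, pairs) {
  writeLines(sprintf("%s\t%s", pairs$from, pairs$to), path)
  invisible(path)
}

#' Read a square similarity matrix with id header row and column
#'
#' @param path Path to the TSV; first row and first column carry identifiers.
#'
#' @return Numeric matrix with identifier dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(ids, colnames(m))) {
    dp_validation_error(sprintf("%s is not a square id-labelled matrix", path))
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Write a square similarity matrix with id header row and column
#'
#' @param path Output path.
#' @param m Square numeric matrix with identifier dimnames.
#' @export
write_similarity_matrix <- function(path, m) {
  ids <- rownames(m)
  header <- paste(c("id", ids), collapse = "\t")
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], format_num(m[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read hashed fingerprints from a bit-index file
#'
#' Each line is `drug_id<TAB>comma-separated bit indices`.
#'
#' @param path Path to the fingerprint TSV.
#'
#' @return A list of [fingerprint()] objects.
#' @export
read_fingerprints <- function(path) {
  lines <- read_tsv_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) dp_validation_error(sprintf("empty fingerprint file: %s", path))
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1) dp_parse_error(sprintf("malformed fingerprint at line %d", i))
    bits <- if (length(parts) >= 2 && nzchar(parts[2])) {
      as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    } else integer(0)
    if (anyNA(bits)) dp_parse_error(sprintf("non-integer bit index at line %d of %s", i, path))
    fingerprint(parts[1], bits)
  })
}

#' Write fingerprints to a bit-index file
#'
#' @param path Output path.
#' @param fps List of [fingerprint()] objects.
#' @export
write_fingerprints <- function(path, fps) {
  lines <- vapply(fps, function(fp) {
    sprintf("%s\t%s", fp$drug_id, paste(fp$bits, collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ranked drug table
#'
#' Writes `drug_id`, `probability`, `z_score` and `significant` columns;
#' output is byte-identical across runs for identical input.
#'
#' @param path Output path.
#' @param rows Data frame with columns `drug_id`, `probability`, `z`,
#'   `significant`, sorted by `z` descending.
#' @export
write_ranking <- function(path, rows) {
  header <- "drug_id\tprobability\tz_score\tsignificant"
  body <- if (nrow(rows)) {
    sprintf("%s\t%s\t%s\t%s", rows$drug_id, format_num(rows$probability),
            format_num(rows$z), ifelse(rows$significant, "true", "false"))
  } else character(0)
  out <- tryCatch(writeLines(c(header, body), path), error = function(e) {
    dp_stop(sprintf("cannot write ranking to %s: %s", path, conditionMessage(e)),
            "drugprop_io_error")
  })
  invisible(path)
}

#' Read a ranked drug table written by [write_ranking()]
#'
#' @param path Path to a ranking TSV.
#' @return Data frame with columns `drug_id`, `probability`, `z`, `significant`.
#' @export
read_ranking <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(drug_id = as.character(df$drug_id),
             probability = as.numeric(df$probability),
             z = as.numeric(df$z_score),
             significant = df$significant == "true",
             stringsAsFactors = FALSE)
}

# Deterministic numeric formatting shared by all writers: 15 significant
# digits round-trips doubles through text for every value the pipeline emits.
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}
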