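#' Construct a two-group expression dataset
#'
#' Bundles a feature-by-sample numeric matrix with a two-group sample
#' labelling. The first group encountered in `labels` is taken as group X;
#' difference scores downstream are oriented as X minus Y, so group order is
#' part of the contract and is preserved by all I/O round trips.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#' @param labels Character (or factor) vector of length `ncol(values)` giving
#'   each sample's group; exactly two distinct groups, each with at least two
#'   samples.
#' @param feature_ids Optional unique feature identifiers (defaults to
#'   rownames or `f1..fM`).
#' @param sample_ids Optional unique sample identifiers (defaults to colnames
#'   or `s1..sW`).
#'
#' @return An object of class `expr_dataset`: a list with elements `values`
#'   (matrix with dimnames set), `labels` (factor whose first level is group
#'   X), `groups` (the two group names, X first).
#' @export
expression_dataset <- function(values, labels, feature_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop_input("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_input("missing value: expression matrix contains NA or non-finite cells")
  }
  M <- nrow(values); W <- ncol(values)
  if (M < 1L) stop_input("at least one feature is required")
  if (W < 2L) stop_input("at least two samples are required")

  feature_ids <- feature_ids %||% rownames(values) %||% paste0("f", seq_len(M))
  sample_ids  <- sample_ids  %||% colnames(values) %||% paste0("s", seq_len(W))
  if (length(feature_ids) != M) stop_input("feature_ids length does not match matrix")
  if (length(sample_ids) != W) stop_input("sample_ids length does not match matrix")
  if (anyDuplicated(feature_ids)) {
    stop_input("duplicated feature ID: %s", feature_ids[duplicated(feature_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop_input("duplicated sample ID: %s", sample_ids[duplicated(sample_ids)][1L])
  }

  labels <- as.character(labels)
  if (length(labels) != W) stop_input("labels length does not match number of samples")
  groups <- unique(labels)
  if (length(groups) != 2L) {
    stop_input("labels must contain exactly two groups, found %d (%s)",
               length(groups), if (length(groups) > 2L) "more than two groups" else "fewer than two groups")
  }
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes < 2L)) {
    stop_input("group '%s' has fewer than 2 samples", names(sizes)[sizes < 2L][1L])
  }

  dimnames(values) <- list(feature_ids, sample_ids)
  structure(
    list(values = values,
         labels = factor(labels, levels = groups),
         groups = groups),
    class = "expr_dataset"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.expr_dataset <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<expr_dataset> %d features x %d samples\n", nrow(x$values), ncol(x$values)))
  cat(sprintf("  groups: %s (X, n=%d) vs %s (Y, n=%d)\n",
              x$groups[1], sizes[[1]], x$groups[2], sizes[[2]]))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

# column indices of the two groups, X first
group_indices <- function(dataset) {
  list(x = which(dataset$labels == dataset$groups[1]),
       y = which(dataset$labels == dataset$groups[2]))
}

#' Read an expression matrix and its sample labels
#'
#' The matrix file is tab-separated with a header row of sample IDs and a
#' first column of feature IDs. The labels file is a two-column TSV
#' (`sample_id`, `group`) with a header; every sample in the matrix must
#' appear there, with exactly two groups overall. Group X is the first group
#' encountered in the labels file (row order), regardless of matrix column
#' order, so orientation of the difference scores is deterministic.
#'
#' @param matrix_path Path to the TSV expression matrix.
#' @param labels_path Path to the TSV labels file.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, labels_path) {
  raw <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L) stop_input("matrix file needs a feature-ID column plus samples")
  feature_ids <- raw[[1L]]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  if (any(is.na(cells)) || any(trimws(cells) == "")) {
    stop_input("missing value in expression matrix")
  }
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(values)) stop_input("non-numeric cell in expression matrix")
  colnames(values) <- colnames(cells)

  lab <- utils::read.delim(labels_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(lab) < 2L) stop_input("labels file needs columns sample_id and group")
  lab_map <- stats::setNames(lab[[2L]], lab[[1L]])
  missing <- setdiff(colnames(values), names(lab_map))
  if (length(missing) > 0L) {
    stop_input("sample '%s' in matrix missing from labels file", missing[1L])
  }
  groups_in_file_order <- unique(lab[[2L]][lab[[1L]] %in% colnames(values)])
  if (length(groups_in_file_order) > 2L) stop_input("more than two groups in labels file")
  labels <- unname(lab_map[colnames(values)])
  ds <- expression_dataset(values, labels, feature_ids = feature_ids,
                           sample_ids = colnames(values))
  # force X = first group by labels-file order, not matrix column order
  ds$groups <- groups_in_file_order
  ds$labels <- factor(as.character(ds$labels), levels = groups_in_file_order)
  ds
}

#' Write an expression dataset back to TSV files
#'
#' Inverse of [read_expression()]: writes the matrix with a feature-ID first
#' column and a labels file whose row order preserves group orientation
#' (group X samples first).
#'
#' @param dataset An `expr_dataset`.
#' @param matrix_path,labels_path Output paths.
#' @return `dataset`, invisibly.
#' @export
write_expression <- function(dataset, matrix_path, labels_path) {
  stopifnot(inherits(dataset, "expr_dataset"))
  df <- data.frame(feature_id = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ord <- order(match(dataset$labels, dataset$groups))
  lab <- data.frame(sample_id = colnames(dataset$values)[ord],
                    group = as.character(dataset$labels)[ord])
  utils::write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dataset)
}

#' Assemble a significance-call result table
#'
#' A `result_table` is a tibble of per-feature rows (`feature_id`, `d_value`,
#' `sign`, `called`) carrying header metadata (N+, N-, estimated FDR, pi0, B,
#' seed) as an attribute. Called `+` rows must be the `n_pos` features with
#' the largest d-values and called `-` rows the `n_neg` smallest (ties broken
#' by feature order).
#'
#' @param features Tibble/data frame with columns `feature_id`, `d_value`,
#'   `sign` (one of `"+"`, `"-"`), `called` (logical).
#' @param meta Named list with elements `n_pos`, `n_neg`, `fdr`, `pi0`, `B`,
#'   `seed`.
#' @return A `result_table` tibble.
#' @export
result_table <- function(features, meta) {
  features <- as_tibble(features)
  needed <- c("feature_id", "d_value", "sign", "called")
  if (!all(needed %in% names(features))) {
    stop_input("result table needs columns: %s", paste(needed, collapse = ", "))
  }
  for (k in c("n_pos", "n_neg", "fdr", "pi0", "B", "seed")) {
    if (is.null(meta[[k]])) stop_input("result metadata missing '%s'", k)
  }
  validate_result_table(features, meta)
  structure(features, meta = meta, class = c("result_table", class(features)))
}

validate_result_table <- function(features, meta) {
  pos_called <- features$called & features$sign == "+"
  neg_called <- features$called & features$sign == "-"
  if (sum(pos_called) != meta$n_pos) {
    stop_input("called '+' rows (%d) do not match header N+ (%d)",
               sum(pos_called), meta$n_pos)
  }
  if (sum(neg_called) != meta$n_neg) {
    stop_input("called '-' rows (%d) do not match header N- (%d)",
               sum(neg_called), meta$n_neg)
  }
  # called + rows must be the n_pos largest d-values (ties by row order)
  if (meta$n_pos > 0L) {
    ord <- order(-features$d_value, seq_len(nrow(features)))
    if (!setequal(which(pos_called), ord[seq_len(meta$n_pos)])) {
      stop_input("called '+' rows are not the N+ largest d-values")
    }
  }
  if (meta$n_neg > 0L) {
    ord <- order(features$d_value, seq_len(nrow(features)))
    if (!setequal(which(neg_called), ord[seq_len(meta$n_neg)])) {
      stop_input("called '-' rows are not the N- smallest d-values")
    }
  }
  invisible(TRUE)
}

#' Write / read a result table
#'
#' Tab-separated, with header metadata in leading `# key<TAB>value` comment
#' lines. Re-reading reproduces the text fields exactly and the reals to full
#' printed precision (17 significant digits).
#'
#' @param result A [result_table()].
#' @param path Output path.
#' @return `result` invisibly (`write_results`); a `result_table`
#'   (`read_results`).
#' @export
write_results <- function(result, path) {
  stopifnot(inherits(result, "result_table"))
  meta <- attr(result, "meta")
  validate_result_table(result, meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("n_pos", "n_neg", "fdr", "pi0", "B", "seed")) {
    writeLines(sprintf("# %s\t%s", k, format(meta[[k]], digits = 17)), con)
  }
  df <- as.data.frame(result)
  df$d_value <- sprintf("%.17g", df$d_value)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- strsplit(sub("^# ", "", ln), "\t", fixed = TRUE)[[1L]]
    meta[[kv[1L]]] <- as.numeric(kv[2L])
  }
  body <- utils::read.delim(text = lines[-hdr], sep = "\t",
                            colClasses = c("character", "character", "character", "logical"))
  features <- tibble(feature_id = body$feature_id,
                     d_value = as.numeric(body$d_value),
                     sign = body$sign,
                     called = body$called)
  result_table(features, meta)
}
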