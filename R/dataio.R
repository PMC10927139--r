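#' Construct an expression dataset
#'
#' Bundles a samples x features expression matrix with one class label per
#' sample. Labels may be strings, factors, or integers; they are mapped
#' internally to contiguous integer codes in order of first appearance so that
#' repeated runs are reproducible regardless of label spelling.
#'
#' @param expression Numeric matrix, rows = samples, columns = features.
#' @param labels Vector of class labels, one per row of `expression`.
#' @param feature_ids Character vector of unique feature identifiers
#'   (default: column names, or `f1..fp`).
#' @param sample_ids Character vector of unique sample identifiers
#'   (default: row names, or `s1..sn`).
#' @param require_multiclass If `TRUE` (default) at least two distinct classes
#'   are required, as any supervised operation needs.
#'
#' @return An object of class `expression_dataset` with elements `expression`,
#'   `labels` (integer codes 1..m), `classes` (original label per code),
#'   `feature_ids`, `sample_ids`.
#' @export
expression_dataset <- function(expression, labels, feature_ids = NULL,
                               sample_ids = NULL, require_multiclass = TRUE) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression)) {
    stop_validation("expression matrix must be numeric")
  }
  if (length(labels) != nrow(expression)) {
    stop_validation("number of labels (", length(labels),
                    ") must equal number of samples (", nrow(expression), ")")
  }
  if (anyNA(expression) || any(!is.finite(expression))) {
    stop_validation("expression matrix contains missing or non-finite values; ",
                    "use read_dataset(impute = \"feature_mean\") or clean the input")
  }
  classes <- unique(as.character(labels))
  codes <- match(as.character(labels), classes)
  if (require_multiclass && length(classes) < 2) {
    stop_validation("at least two classes are required (got ", length(classes), ")")
  }
  cn <- colnames(expression)
  if (!is.null(cn) && any(!nzchar(cn))) cn <- NULL  # partial names: discard
  feature_ids <- feature_ids %||% cn %||% paste0("f", seq_len(ncol(expression)))
  sample_ids <- sample_ids %||% rownames(expression) %||%
    paste0("s", seq_len(nrow(expression)))
  if (anyDuplicated(feature_ids)) stop_validation("feature_ids must be distinct")
  if (anyDuplicated(sample_ids)) stop_validation("sample_ids must be distinct")
  if (length(feature_ids) != ncol(expression)) {
    stop_validation("feature_ids length must equal number of features")
  }
  if (length(sample_ids) != nrow(expression)) {
    stop_validation("sample_ids length must equal number of samples")
  }
  dimnames(expression) <- NULL
  structure(
    list(expression = expression, labels = codes, classes = classes,
         feature_ids = as.character(feature_ids),
         sample_ids = as.character(sample_ids)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d features, %d classes\n",
              nrow(x$expression), ncol(x$expression), length(x$classes)))
  counts <- table(factor(x$labels, levels = seq_along(x$classes), labels = x$classes))
  cat("class counts:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$expression)

#' Read an expression dataset from delimited text
#'
#' Expects a rectangular table with a header row; one column holds the class
#' label and the remaining columns hold numeric expression values. Feature and
#' sample order are preserved exactly as in the file.
#'
#' @param path Path to a CSV/TSV file.
#' @param label_column Name of the label column, or `"last"` (default) for the
#'   final column.
#' @param delimiter Field delimiter (default `","`).
#' @param transpose If `TRUE`, the file is features x samples and is transposed
#'   after reading (the label row is then identified by `label_column` among
#'   the row names). Default `FALSE`.
#' @param impute Either `"none"` (default; missing values are an error) or
#'   `"feature_mean"` to replace missing entries by the feature mean.
#'
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(path, label_column = "last", delimiter = ",",
                         transpose = FALSE, impute = c("none", "feature_mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE, blank.lines.skip = FALSE,
                          colClasses = NA)
  if (transpose) {
    ids <- df[[1]]
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- ids
    df <- cbind(sample_id = rownames(mat), df, stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  if (identical(label_column, "last")) label_column <- names(df)[ncol(df)]
  if (!label_column %in% names(df)) {
    stop_validation("label column '", label_column, "' not found; available: ",
                    paste(names(df), collapse = ", "))
  }
  labels <- df[[label_column]]
  feat_df <- df[, setdiff(names(df), label_column), drop = FALSE]
  # a leading non-numeric column (e.g. sample_id) supplies sample ids
  sample_ids <- NULL
  if (ncol(feat_df) > 0) {
    first <- feat_df[[1]]
    if (!is.numeric(first) && !anyNA(first) &&
        all(is.na(suppressWarnings(as.numeric(first))))) {
      sample_ids <- as.character(first)
      feat_df <- feat_df[, -1, drop = FALSE]
    }
  }
  mat <- matrix(NA_real_, nrow(feat_df), ncol(feat_df))
  for (j in seq_len(ncol(feat_df))) {
    col <- feat_df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & trimws(as.character(col)) != "" &
                   tolower(trimws(as.character(col))) != "na")
    if (length(bad) > 0) {
      stop_validation("non-numeric expression value '", col[bad[1]],
                      "' at row ", bad[1], ", column '", names(feat_df)[j], "'")
    }
    mat[, j] <- num
  }
  if (anyNA(mat)) {
    if (impute == "none") {
      idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
      stop_validation("missing value at row ", idx[1], ", column '",
                      names(feat_df)[idx[2]], "'; set impute = \"feature_mean\" to impute")
    }
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- mean(mat[!nas, j])
    }
  }
  expression_dataset(mat, labels, feature_ids = names(feat_df),
                     sample_ids = sample_ids)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_dataset()]: writes a header row, one row per sample, the
#' label in the final column. Values are written with 12 significant digits so
#' a read/write round trip is lossless at that precision.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @export
write_dataset <- function(dataset, path, delimiter = ",") {
  mat <- format(dataset$expression, digits = 12, trim = TRUE, scientific = FALSE)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- dataset$feature_ids
  df$label <- dataset$classes[dataset$labels]
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a selection result to CSV
#'
#' Emits a metadata header block of `# key=value` comment lines (seed, config
#' hash, accuracy, feature scale) followed by one row per selected feature:
#' `feature_id,ig_value,group_index`.
#'
#' @param result A `selection_result` from [run_gpso()], [pso_select()] or
#'   [hybrid_select()].
#' @param path Output file path.
#' @export
write_selection <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(seed = result$seed %||% NA,
            config_hash = config_hash(result$config_snapshot %||% list()),
            acc = format(result$acc, digits = 12),
            fs = result$fs)
  writeLines(paste0("# ", names(meta), "=", unlist(meta)), con)
  writeLines("feature_id,ig_value,group_index", con)
  if (length(result$selected) == 0) {
    warning("empty selection: writing header-only file")
  } else {
    writeLines(paste(result$feature_ids,
                     format(result$ig_values, digits = 12, trim = TRUE),
                     result$group_index, sep = ","), con)
  }
  invisible(path)
}

#' Read back a selection CSV written by [write_selection()]
#'
#' @param path Path to a selection CSV.
#' @return Data frame with columns `feature_id`, `ig_value`, `group_index`,
#'   and the metadata block as a `metadata` attribute.
#' @export
read_selection <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", meta_lines)
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  attr(df, "metadata") <- as.list(meta)
  df
}

#' Read an algorithm x dataset score table
#'
#' The expected layout mirrors published benchmark tables: first column the
#' dataset name, a `direction` column flagging each row as `higher_better`
#' (e.g. accuracy) or `lower_better` (e.g. subset size), and one column of
#' scores per algorithm.
#'
#' @param path Path to a delimited score table.
#' @param delimiter Field delimiter (default `","`).
#' @return A [rank_table()].
#' @export
read_score_table <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE)
  if (!"direction" %in% names(df)) {
    stop_validation("score table must contain a 'direction' column ",
                    "(higher_better/lower_better per row)")
  }
  direction <- df$direction
  row_labels <- as.character(df[[1]])
  score_cols <- setdiff(names(df), c(names(df)[1], "direction"))
  values <- as.matrix(df[, score_cols, drop = FALSE])
  if (!is.numeric(values)) stop_validation("score columns must be numeric")
  rank_table(values, direction, row_labels = row_labels,
             column_labels = score_cols)
}

#' Write a rank table as CSV in the layout [read_score_table()] expects
#'
#' @param table A [rank_table()].
#' @param path Output file path.
#' @export
write_score_table <- function(table, path) {
  df <- data.frame(dataset = table$row_labels,
                   direction = table$row_direction,
                   table$values, check.names = FALSE)
  colnames(df)[-(1:2)] <- table$column_labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
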