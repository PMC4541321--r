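#' Labeled feature matrix
#'
#' Container pairing a numeric features x samples matrix with a two-phenotype
#' sample labeling. Used for gene expression, metabolite abundances and
#' pathway-activity profiles alike.
#'
#' @param values numeric matrix, features in rows, samples in columns. Row
#'   names are feature ids, column names are sample ids.
#' @param labels phenotype per sample: a character/factor vector with exactly
#'   two levels, either named by sample id or in column order of `values`.
#' @return an object of class `labeled_matrix`: a list with elements
#'   `values` (the matrix) and `labels` (a factor aligned to the columns).
#' @export
labeled_matrix <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row names (features) and column names (samples)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in `values`")
  if (!is.null(names(labels))) {
    missing <- setdiff(colnames(values), names(labels))
    if (length(missing))
      stop("samples without labels: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
  } else if (length(labels) != ncol(values)) {
    stop("`labels` length does not match the number of samples")
  }
  labels <- factor(as.character(labels))
  if (anyNA(labels)) stop("missing phenotype labels")
  if (nlevels(labels) != 2)
    stop("exactly two phenotypes required, got: ",
         paste(levels(labels), collapse = ", "))
  names(labels) <- colnames(values)
  structure(list(values = values, labels = labels), class = "labeled_matrix")
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Restrict a labeled matrix to a subset of samples
#'
#' @param m a [labeled_matrix()]
#' @param samples sample ids or column indices to keep
#' @return a `labeled_matrix` over the selected samples
#' @export
subset_samples <- function(m, samples) {
  labeled_matrix(m$values[, samples, drop = FALSE], m$labels[samples])
}

#' Read / write a feature matrix as TSV
#'
#' The format is a header row of sample ids preceded by a feature-id column,
#' one row per feature, tab-separated, UTF-8, LF line endings.
#'
#' @param path file path
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix TSV needs a feature-id column and >= 1 sample")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @param m numeric matrix with dimnames
#' @param feature_col header name for the id column
#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path, feature_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample labels as TSV
#'
#' Two columns: sample_id and phenotype, tab-separated with a header.
#'
#' @param path file path
#' @return `read_labels_tsv`: a named character vector of phenotypes.
#' @export
read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("labels TSV needs columns sample_id and phenotype")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @param labels named character vector, sample id -> phenotype
#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), phenotype = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
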