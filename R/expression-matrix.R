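#' Construct a time-course expression matrix
#'
#' An `ExpressionMatrix` is a real-valued genes-by-time-points matrix with
#' unique gene identifiers on the rows and ordered time-point labels on the
#' columns. It is the common input of all five discretization methods and of
#' the fold-change node ordering.
#'
#' @param values Numeric matrix, genes in rows, time points in columns.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param time_labels Character vector of time-point labels in temporal order
#'   (defaults to `colnames(values)`).
#' @return A numeric matrix of class `ExpressionMatrix` with `dimnames` set.
#' @examples
#' m <- expression_matrix(matrix(1:6, 2, 3), c("G1", "G2"), c("t1", "t2", "t3"))
#' dim(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              time_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(nrow(values)))
  if (is.null(time_labels)) time_labels <- paste0("T", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  time_labels <- as.character(time_labels)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("an ExpressionMatrix needs at least 2 genes and 2 time points")
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match the number of rows")
  if (length(time_labels) != ncol(values))
    stop("time_labels length does not match the number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyNA(values))
    stop("missing values in expression matrix; impute before construction ",
         "or use read_expression(impute = TRUE)")
  dimnames(values) <- list(gene_ids, time_labels)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d time points\n", nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE],
                    6L), ...)
  invisible(x)
}

#' Read a time-course expression matrix from delimited text
#'
#' The expected dialect is UTF-8 delimited text with a header row of time
#' labels and the gene identifier in the first column; the body must be
#' numeric. Missing values are rejected unless `impute = TRUE`, in which case
#' they are filled per gene by linear interpolation along time (constant
#' extrapolation at the ends).
#'
#' @param path Path to the file.
#' @param delimiter Field separator, tab by default.
#' @param impute Logical; interpolate missing values instead of failing.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, delimiter = "\t", impute = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "", row.names = NULL)
  if (ncol(df) < 3L) stop("expected gene-id column plus >= 2 time columns")
  gene_ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  vals <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  vals <- matrix(vals, nrow = nrow(body))
  raw <- as.matrix(body)
  bad <- which(is.na(vals) & !is.na(raw) & !(toupper(raw) %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at gene '%s', time column '%s'",
                 as.matrix(body)[bad[1L, 1L], bad[1L, 2L]],
                 gene_ids[bad[1L, 1L]], colnames(body)[bad[1L, 2L]]))
  if (anyNA(vals)) {
    if (!impute)
      stop("missing values present; pass impute = TRUE to interpolate")
    vals <- t(apply(vals, 1L, .impute_linear))
  }
  expression_matrix(vals, gene_ids, colnames(body))
}

.impute_linear <- function(v) {
  if (!anyNA(v)) return(v)
  obs <- which(!is.na(v))
  if (length(obs) == 0L) stop("gene with no observed values cannot be imputed")
  stats::approx(obs, v[obs], xout = seq_along(v), rule = 2L)$y
}

#' Write an expression matrix as tab-separated text
#'
#' The output round-trips through [read_expression()]. Labels containing the
#' delimiter are quoted.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param delimiter Field separator, tab by default.
#' @export
write_expression <- function(m, path, delimiter = "\t") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene", colnames(m))
  needs_quote <- any(grepl(delimiter, c(rownames(m), colnames(m)), fixed = TRUE))
  utils::write.table(df, path, sep = delimiter, quote = needs_quote,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a discretized expression matrix
#'
#' A `DiscreteMatrix` holds integer interval indices in `1..k` with the same
#' shape and labels as the source expression matrix, together with the number
#' of intervals `k` and a tag naming the discretizer that produced it.
#'
#' @param levels Integer matrix of interval indices.
#' @param k Number of intervals (>= 2).
#' @param method_tag Character scalar naming the discretization method.
#' @return An integer matrix of class `DiscreteMatrix` with attributes `k` and
#'   `method`.
#' @export
discrete_matrix <- function(levels, k, method_tag = "manual") {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "integer"
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (anyNA(levels) || any(levels < 1L) || any(levels > k))
    stop("discrete levels must all lie in 1..k")
  structure(levels, k = k, method = as.character(method_tag),
            class = c("DiscreteMatrix", "matrix", "array"))
}

#' @export
print.DiscreteMatrix <- function(x, ...) {
  cat(sprintf("DiscreteMatrix (%s, k = %d): %d genes x %d time points\n",
              attr(x, "method"), attr(x, "k"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(8L, ncol(x))), drop = FALSE], 6L))
  invisible(x)
}

#' Write / read a discrete matrix as TSV of integer levels
#'
#' @param d A [discrete_matrix()].
#' @param path File path.
#' @rdname discrete_io
#' @export
write_discrete <- function(d, path) {
  stopifnot(inherits(d, "DiscreteMatrix"))
  df <- data.frame(gene = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @param k Number of intervals the file encodes (defaults to the maximum
#'   level observed).
#' @rdname discrete_io
#' @export
read_discrete <- function(path, k = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1L)
  m <- as.matrix(df)
  if (is.null(k)) k <- max(m)
  discrete_matrix(m, k = k, method_tag = "file")
}
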