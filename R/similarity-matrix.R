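#' Labeled symmetric similarity matrix
#'
#' Container for pairwise similarity scores between individuals or markers:
#' kinship or coancestry coefficients, identity-by-descent sharing,
#' linkage-disequilibrium r-squared, or any other non-negative measure where
#' larger means more similar.  Values may exceed 1.  The diagonal
#' (self-similarity) is carried but never used when building a graph.
#'
#' @param values numeric square matrix of similarities; must be symmetric
#'   within `tol` and non-negative off the diagonal.
#' @param labels character vector of unique, non-empty entity identifiers,
#'   one per row.  Defaults to `rownames(values)`.
#' @param tol absolute tolerance for the symmetry check.
#' @return An object of class `similarity_matrix`: the numeric matrix with
#'   `labels` as dimnames.
#' @examples
#' m <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
#' similarity_matrix(m, c("ind1", "ind2"))
#' @seealso [read_similarity_matrix()], [threshold_graph()]
#' @export
similarity_matrix <- function(values, labels = rownames(values), tol = 1e-9) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(values)
  if (ncol(values) != n) {
    stop(sprintf("matrix must be square; got %d rows and %d columns",
                 n, ncol(values)), call. = FALSE)
  }
  if (is.null(labels)) {
    stop("entity labels are required (supply 'labels' or rownames)",
         call. = FALSE)
  }
  labels <- as.character(labels)
  validate_labels(labels, n)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at cell (%d,%d)", bad[1L], bad[2L]),
         call. = FALSE)
  }
  check_offdiag_nonneg(values)
  check_symmetry(values, tol)
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("similarity_matrix", "matrix", "array"))
}

validate_labels <- function(labels, n) {
  if (length(labels) != n) {
    stop(sprintf("%d labels supplied for a %dx%d matrix", length(labels), n, n),
         call. = FALSE)
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    stop("labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop(sprintf("duplicated label '%s'", dup), call. = FALSE)
  }
  invisible(labels)
}

check_offdiag_nonneg <- function(values) {
  v <- values
  diag(v) <- 0
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative off-diagonal value %g at cell (%d,%d)",
                 values[bad[1L], bad[2L]], bad[1L], bad[2L]), call. = FALSE)
  }
  invisible(values)
}

check_symmetry <- function(values, tol) {
  d <- abs(values - t(values))
  if (any(d > tol)) {
    bad <- which(d > tol, arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE][1L, ]
    stop(sprintf(
      "matrix not symmetric: cell (%d,%d)=%g but cell (%d,%d)=%g",
      bad[1L], bad[2L], values[bad[1L], bad[2L]],
      bad[2L], bad[1L], values[bad[2L], bad[1L]]), call. = FALSE)
  }
  invisible(values)
}

#' @export
print.similarity_matrix <- function(x, ...) {
  n <- nrow(x)
  off <- x[upper.tri(x)]
  cat(sprintf("Similarity matrix: %d entities\n", n))
  if (length(off)) {
    cat(sprintf("  off-diagonal values: min %.4g, median %.4g, max %.4g\n",
                min(off), stats::median(off), max(off)))
  }
  cat("  labels:", paste(utils::head(rownames(x), 6L), collapse = " "),
      if (n > 6L) "..." else "", "\n")
  invisible(x)
}

#' Read a labeled similarity matrix from a text file
#'
#' The format mirrors a whitespace-separated data frame dump: the first
#' non-blank line holds the N column labels, and each of the following N
#' lines holds a row label followed by N numeric values.  Row labels must
#' repeat the column labels in the same order.  Fields are separated by any
#' run of spaces or tabs; trailing whitespace is ignored.
#'
#' Validation failures (header/row dimension mismatch, row/column label
#' disagreement, non-numeric fields, negative off-diagonal values, asymmetry
#' beyond `tol`) raise an error naming the offending line or cell.
#'
#' @param path path to the matrix file.
#' @param tol absolute symmetry tolerance.
#' @return A [similarity_matrix()].
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "a 1 0.2", "b 0.2 1"), f)
#' read_similarity_matrix(f)
#' @export
read_similarity_matrix <- function(path, tol = 1e-9) {
  if (!file.exists(path)) {
    stop(sprintf("matrix file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop(sprintf("'%s': need a header line and at least one row", path),
         call. = FALSE)
  }
  split_ws <- function(s) strsplit(trimws(s), "[ \t]+")[[1L]]
  labels <- split_ws(lines[1L])
  n <- length(labels)
  if (length(lines) - 1L != n) {
    stop(sprintf("header names %d entities but file has %d data rows",
                 n, length(lines) - 1L), call. = FALSE)
  }
  values <- matrix(NA_real_, n, n)
  row_labels <- character(n)
  for (i in seq_len(n)) {
    fields <- split_ws(lines[i + 1L])
    if (length(fields) != n + 1L) {
      stop(sprintf("line %d: expected a row label plus %d values, found %d fields",
                   i + 1L, n, length(fields)), call. = FALSE)
    }
    row_labels[i] <- fields[1L]
    v <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop(sprintf("line %d: non-numeric field '%s' in column %d",
                   i + 1L, fields[j + 1L], j), call. = FALSE)
    }
    values[i, ] <- v
  }
  if (!identical(row_labels, labels)) {
    j <- which(row_labels != labels)[1L]
    stop(sprintf("row label '%s' (line %d) does not match column label '%s'",
                 row_labels[j], j + 1L, labels[j]), call. = FALSE)
  }
  similarity_matrix(values, labels, tol = tol)
}

#' Write a labeled similarity matrix to a text file
#'
#' Inverse of [read_similarity_matrix()].  Values are written with `%.17g`
#' so that doubles round-trip exactly and re-serialization of a re-read
#' matrix is byte-identical.
#'
#' @param x a [similarity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "similarity_matrix"))
  labels <- rownames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = " "), con)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(labels[i], paste(sprintf("%.17g", x[i, ]), collapse = " "))
  }, character(1L))
  writeLines(rows, con)
  invisible(path)
}
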