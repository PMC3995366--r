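#' Random uniform similarity matrix
#'
#' Simulation input for calibration studies: each unordered pair of
#' entities receives one independent U(0,1) draw, copied to both symmetric
#' cells; the diagonal is fixed at 1 (the conventional self-similarity of
#' coancestry-like measures, and ignored by [threshold_graph()] anyway).
#' Labels follow the fixed scheme `N0001`, `N0002`, ... so written fixtures
#' are reproducible.
#'
#' Thresholding such a matrix at `t` yields, statistically, an
#' Erdos-Renyi G(n, 1 - t) random graph: threshold plus expected
#' connectivity is 1.
#'
#' @param n number of entities (>= 2).
#' @param seed optional integer seed; `NULL` uses the current random number
#'   stream.
#' @return A [similarity_matrix()].
#' @examples
#' random_similarity_matrix(4, seed = 1)
#' @export
random_similarity_matrix <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be >= 2", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  values <- matrix(0, n, n)
  values[upper.tri(values)] <- stats::runif(n * (n - 1L) / 2L)
  values <- values + t(values)
  diag(values) <- 1
  similarity_matrix(values, sprintf("N%04d", seq_len(n)))
}

#' Random threshold graph
#'
#' Convenience wrapper: [random_similarity_matrix()] followed by
#' [threshold_graph()].  The result is statistically an Erdos-Renyi
#' G(n, p = 1 - threshold) graph.
#'
#' @inheritParams random_similarity_matrix
#' @param threshold edge threshold in \[0, 1\].
#' @return A [threshold_graph()].
#' @export
random_threshold_graph <- function(n, threshold, seed = NULL) {
  threshold_graph(random_similarity_matrix(n, seed = seed), threshold)
}
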