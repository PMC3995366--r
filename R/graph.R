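#' Build the threshold graph of a similarity matrix
#'
#' Assigns a node to each entity and joins two nodes by an (undirected,
#' unweighted) edge exactly when their similarity is strictly greater than
#' the threshold.  Ties at the threshold are non-edges.  An independent set
#' of this graph is therefore a set of mutually *unrelated* entities.
#'
#' Thresholds are restricted to \[0, 1\] even though similarities may exceed
#' 1; pairs with similarity above 1 are joined at every threshold.
#'
#' @param sim a [similarity_matrix()].
#' @param threshold edge threshold in \[0, 1\].
#' @return An object of class `threshold_graph`: a list with elements
#'   `labels`, `adjacency` (symmetric logical matrix, `FALSE` diagonal) and
#'   `threshold`.
#' @examples
#' m <- similarity_matrix(matrix(c(1, .6, .1, .6, 1, .2, .1, .2, 1), 3, 3),
#'                        c("a", "b", "c"))
#' g <- threshold_graph(m, 0.5)
#' connectivity(g)
#' @export
threshold_graph <- function(sim, threshold) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("'threshold' must be a single number in [0, 1]", call. = FALSE)
  }
  adj <- unclass(sim) > threshold
  diag(adj) <- FALSE
  structure(list(labels = rownames(sim), adjacency = adj,
                 threshold = threshold),
            class = "threshold_graph")
}

# Internal constructor for tests/helpers: graph straight from a logical
# adjacency matrix (symmetrized, diagonal cleared).
graph_from_adjacency <- function(adj, labels = rownames(adj),
                                 threshold = NA_real_) {
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  if (is.null(labels)) labels <- sprintf("V%03d", seq_len(nrow(adj)))
  dimnames(adj) <- list(labels, labels)
  structure(list(labels = labels, adjacency = adj, threshold = threshold),
            class = "threshold_graph")
}

n_nodes <- function(graph) length(graph$labels)

graph_degrees <- function(graph) colSums(graph$adjacency)

#' @export
print.threshold_graph <- function(x, ...) {
  n <- n_nodes(x)
  e <- sum(x$adjacency) / 2
  cat(sprintf("Threshold graph: %d nodes, %d edges (threshold %s)\n",
              n, e, format(x$threshold)))
  if (n >= 2L) cat(sprintf("  connectivity: %.4f\n", connectivity(x)))
  p <- partition_nodes(x)
  cat(sprintf("  isolated %d | regular %d | universal %d\n",
              length(p$isolated), length(p$regular), length(p$universal)))
  invisible(x)
}

#' Graph connectivity (edge density)
#'
#' The ratio of the number of edges present to the `n(n-1)/2` edges a
#' complete graph on the same nodes would have: 0 for an edgeless graph,
#' 1 for a complete graph.  For graphs built by thresholding a uniform
#' random similarity matrix at `t`, connectivity is approximately `1 - t`.
#'
#' @param graph a [threshold_graph()] with at least two nodes.
#' @return A fraction in \[0, 1\].
#' @export
connectivity <- function(graph) {
  stopifnot(inherits(graph, "threshold_graph"))
  n <- n_nodes(graph)
  if (n < 2L) {
    stop("connectivity is undefined for a graph with fewer than 2 nodes",
         call. = FALSE)
  }
  (sum(graph$adjacency) / 2) / (n * (n - 1) / 2)
}

#' Non-neighbor counts
#'
#' For each node, the number of other nodes it is *not* adjacent to
#' (`n - 1 - degree`).  These counts drive the randomized selection rule:
#' a node disconnected from many others is a good seed for a large
#' independent set.
#'
#' @param graph a [threshold_graph()].
#' @return Named integer vector, one count per node in node order.
#' @export
non_neighbor_counts <- function(graph) {
  stopifnot(inherits(graph, "threshold_graph"))
  n <- n_nodes(graph)
  counts <- as.integer((n - 1L) - graph_degrees(graph))
  names(counts) <- graph$labels
  counts
}

#' Partition nodes into isolated, universal and regular
#'
#' Isolated nodes (degree 0) belong to every maximal independent set and are
#' added to the output automatically; universal nodes (adjacent to all
#' others) belong to no multi-node independent set and are excluded from
#' sampling; the remaining regular nodes are what the heuristic works on.
#' In a 1-node graph the node is isolated.
#'
#' @param graph a [threshold_graph()].
#' @return A list with character vectors `isolated`, `universal`, `regular`
#'   (disjoint, covering all node labels).
#' @export
partition_nodes <- function(graph) {
  stopifnot(inherits(graph, "threshold_graph"))
  n <- n_nodes(graph)
  deg <- graph_degrees(graph)
  isolated <- deg == 0L
  universal <- !isolated & deg == n - 1L
  list(isolated = graph$labels[isolated],
       universal = graph$labels[universal],
       regular = graph$labels[!isolated & !universal])
}

resolve_labels <- function(graph, s) {
  s <- as.character(s)
  idx <- match(s, graph$labels)
  if (anyNA(idx)) {
    stop(sprintf("unknown node label '%s'", s[which(is.na(idx))[1L]]),
         call. = FALSE)
  }
  idx
}

#' Test whether a node set is independent
#'
#' @param graph a [threshold_graph()].
#' @param s character vector of node labels (a subset of the graph's nodes).
#' @return `TRUE` iff no two members of `s` are adjacent.  The empty set and
#'   all singletons are independent.
#' @export
is_independent <- function(graph, s) {
  stopifnot(inherits(graph, "threshold_graph"))
  idx <- resolve_labels(graph, s)
  if (length(idx) < 2L) return(TRUE)
  !any(graph$adjacency[idx, idx])
}

#' Test whether a node set is a maximal independent set
#'
#' Maximal means no further node can be added without breaking
#' independence: every node outside `s` must have at least one neighbor
#' inside `s`.
#'
#' @inheritParams is_independent
#' @return `TRUE` iff `s` is independent and maximal.
#' @export
is_maximal_independent <- function(graph, s) {
  stopifnot(inherits(graph, "threshold_graph"))
  idx <- resolve_labels(graph, s)
  if (!is_independent(graph, s)) return(FALSE)
  outside <- setdiff(seq_len(n_nodes(graph)), idx)
  if (!length(outside)) return(TRUE)
  if (!length(idx)) return(FALSE)
  covered <- colSums(graph$adjacency[idx, outside, drop = FALSE]) > 0L
  all(covered)
}

#' Dump a graph as an edge list
#'
#' Debug helper: one edge per row, two label columns, each undirected edge
#' listed once with the lexicographically smaller label first.
#'
#' @param graph a [threshold_graph()].
#' @return A two-column character matrix (0 rows for an edgeless graph).
#' @export
as_edge_list <- function(graph) {
  stopifnot(inherits(graph, "threshold_graph"))
  idx <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  a <- graph$labels[idx[, 1L]]
  b <- graph$labels[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  cbind(from = a[ord], to = b[ord])
}
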