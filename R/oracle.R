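budget_error <- function(msg) {
  stop(structure(class = c("indepsel_budget_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_budget_nodes <- function(graph, max_nodes, what) {
  n <- n_nodes(graph)
  if (n > max_nodes) {
    budget_error(sprintf(
      "budget exceeded: %s accepts at most %d nodes, graph has %d (raise 'max_nodes' at your own risk)",
      what, max_nodes, n))
  }
  invisible(n)
}

#' Exact maximum independent set (branch and bound)
#'
#' Finds one independent set of maximum cardinality — the independence
#' number of the graph — by deterministic branch and bound: a maximum
#' clique search on the complement graph, pruned with a greedy-coloring
#' bound (equivalently, a greedy clique cover of the candidate set in the
#' original graph).  Exact but exponential in the worst case, hence the
#' node and wall-time budgets; intended for validating the heuristic on
#' graphs of up to a few hundred nodes.
#'
#' @param graph a [threshold_graph()].
#' @param max_nodes refuse graphs larger than this.
#' @param max_seconds wall-time cap for the search.
#' @return Character vector of node labels in canonical (sorted) order: a
#'   provably maximum independent set.
#' @section Errors: exceeding either budget raises a condition of class
#'   `indepsel_budget_error`, distinct from ordinary failures.
#' @examples
#' g <- random_threshold_graph(30, threshold = 0.5, seed = 1)
#' length(maximum_independent_set(g))
#' @export
maximum_independent_set <- function(graph, max_nodes = 200L,
                                    max_seconds = 60) {
  stopifnot(inherits(graph, "threshold_graph"))
  check_budget_nodes(graph, max_nodes, "the branch-and-bound solver")
  n <- n_nodes(graph)
  if (n == 0L) return(character(0))
  # deterministic vertex order: most non-neighbors first (highest degree on
  # the complement, where the clique search runs), label tie-break
  deg <- graph_degrees(graph)
  ord <- order(deg, graph$labels, method = "radix")
  adj <- graph$adjacency[ord, ord]
  res <- tryCatch(
    .mis_branch_bound(adj, as.numeric(max_seconds)),
    error = function(e) {
      if (grepl("time budget exceeded", conditionMessage(e))) {
        budget_error(sprintf(
          "budget exceeded: branch and bound passed %gs wall-time cap", max_seconds))
      }
      stop(e)
    })
  sort_labels(graph$labels[ord[res]])
}

#' Enumerate all maximal independent sets
#'
#' Bron-Kerbosch with pivoting, run on the complement graph (a maximal
#' clique of the complement is a maximal independent set of the graph).
#' Every maximal independent set is produced exactly once.  The number of
#' maximal sets can grow as 3^(n/3), so this is for small graphs only.
#'
#' @param graph a [threshold_graph()].
#' @param max_nodes refuse graphs larger than this (default 40).
#' @return List of character vectors (canonical order), sorted by
#'   decreasing size then lexicographically.
#' @section Errors: graphs above `max_nodes` raise an
#'   `indepsel_budget_error`.
#' @examples
#' g <- random_threshold_graph(10, threshold = 0.5, seed = 1)
#' enumerate_maximal_sets(g)
#' @export
enumerate_maximal_sets <- function(graph, max_nodes = 40L) {
  stopifnot(inherits(graph, "threshold_graph"))
  check_budget_nodes(graph, max_nodes, "the maximal-set enumerator")
  n <- n_nodes(graph)
  if (n == 0L) return(list())
  comp <- !graph$adjacency
  diag(comp) <- FALSE
  out <- vector("list", 64L)
  n_out <- 0L
  emit <- function(clique) {
    n_out <<- n_out + 1L
    if (n_out > length(out)) length(out) <<- 2L * n_out
    out[[n_out]] <<- clique
  }
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      emit(R)
      return(invisible())
    }
    # pivot: vertex of P union X with most complement-neighbors in P
    px <- c(P, X)
    gain <- vapply(px, function(u) sum(comp[u, P]), numeric(1L))
    u <- px[which.max(gain)]
    for (v in P[!comp[u, P]]) {
      nb <- which(comp[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  sets <- lapply(out[seq_len(n_out)],
                 function(idx) sort_labels(graph$labels[idx]))
  keys <- vapply(sets, set_key, character(1L))
  sets[order(-lengths(sets), keys, method = "radix")]
}
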