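# Fixture builders and independent brute-force oracles.  The oracles work
# from first principles (subset enumeration, explicit recursion over the
# selection rule) so they never share code paths with the implementation
# they check.

sim_from_edges <- function(labels, edges) {
  n <- length(labels)
  m <- matrix(0, n, n)
  dimnames(m) <- list(labels, labels)
  for (e in edges) {
    m[e[1L], e[2L]] <- 1
    m[e[2L], e[1L]] <- 1
  }
  diag(m) <- 1
  similarity_matrix(m, labels)
}

graph_from_edges <- function(labels, edges, threshold = 0.5) {
  threshold_graph(sim_from_edges(labels, edges), threshold)
}

path_graph <- function(labels) {
  k <- length(labels)
  graph_from_edges(labels, Map(c, labels[-k], labels[-1L]))
}

complete_graph <- function(labels) {
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  graph_from_edges(labels, pairs)
}

edgeless_graph <- function(labels) {
  graph_from_edges(labels, list())
}

# adjacency reconstructed from the public edge-list dump
edge_lookup <- function(graph) {
  el <- as_edge_list(graph)
  adjacent <- function(a, b) {
    any((el[, 1L] == a & el[, 2L] == b) | (el[, 1L] == b & el[, 2L] == a))
  }
  labels <- names(non_neighbor_counts(graph))
  list(labels = labels, adjacent = adjacent)
}

# Brute-force maximum independent set over all 2^n subsets (n <= 16).
brute_max_independent_size <- function(graph) {
  lk <- edge_lookup(graph)
  n <- length(lk$labels)
  stopifnot(n <= 16L)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(idx) <= best) next
    s <- lk$labels[idx]
    ok <- TRUE
    if (length(s) >= 2L) {
      pr <- utils::combn(s, 2L)
      for (j in seq_len(ncol(pr))) {
        if (lk$adjacent(pr[1L, j], pr[2L, j])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(idx)
  }
  best
}

# Brute-force enumeration of all maximal independent sets (n <= 12).
brute_maximal_sets <- function(graph) {
  lk <- edge_lookup(graph)
  n <- length(lk$labels)
  stopifnot(n <= 12L)
  indep <- function(s) {
    if (length(s) < 2L) return(TRUE)
    pr <- utils::combn(s, 2L)
    !any(vapply(seq_len(ncol(pr)),
                function(j) lk$adjacent(pr[1L, j], pr[2L, j]), logical(1L)))
  }
  out <- list()
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    s <- lk$labels[idx]
    if (!indep(s)) next
    addable <- vapply(setdiff(lk$labels, s),
                      function(v) indep(c(s, v)), logical(1L))
    if (!any(addable)) out[[length(out) + 1L]] <- sort(s, method = "radix")
  }
  out
}

# Exact output distribution of the randomized selection rule, by explicit
# enumeration of every execution branch of the procedure: seed node drawn
# over regular nodes with weight n_i^gamma, then repeated draws from the
# shrinking candidate set with the same global weights.  Returns
# probabilities keyed by the canonical (sorted, space-joined) set.
branch_probabilities <- function(graph, gamma = 1) {
  lk <- edge_lookup(graph)
  labels <- lk$labels
  n <- length(labels)
  nn <- vapply(labels, function(a) {
    sum(vapply(setdiff(labels, a), function(b) !lk$adjacent(a, b),
               logical(1L)))
  }, numeric(1L))
  isolated <- labels[nn == n - 1L]
  regular <- labels[nn > 0L & nn < n - 1L]
  acc <- new.env(parent = emptyenv())
  add <- function(members, p) {
    p <- as.numeric(p)
    key <- paste(sort(members, method = "radix"), collapse = " ")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + p
  }
  non_neighbors_of <- function(v, pool) {
    pool[vapply(pool, function(b) b != v && !lk$adjacent(v, b), logical(1L))]
  }
  recurse <- function(ret, cand, p) {
    if (!length(cand)) {
      add(c(ret, isolated), p)
      return(invisible())
    }
    w <- nn[cand]^gamma
    w <- w / sum(w)
    for (i in seq_along(cand)) {
      v <- cand[i]
      recurse(c(ret, v), intersect(cand, non_neighbors_of(v, cand)), p * w[i])
    }
  }
  if (!length(regular)) {
    add(isolated, 1)
  } else {
    w0 <- nn[regular]^gamma
    w0 <- w0 / sum(w0)
    for (i in seq_along(regular)) {
      v <- regular[i]
      recurse(v, non_neighbors_of(v, regular), w0[i])
    }
  }
  unlist(as.list(acc))
}

set_keys <- function(sets) {
  vapply(sets, paste, character(1L), collapse = " ")
}
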