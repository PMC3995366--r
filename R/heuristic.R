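# Label sorting and tie-breaks use radix (C-locale) order so results do not
# depend on the session locale.
sort_labels <- function(x) sort(x, method = "radix")

set_key <- function(members) paste(members, collapse = "\x1f")

#' Candidate selection weights
#'
#' Normalized sampling weights over a candidate set: node `i` is drawn with
#' probability proportional to `n_i^gamma`, where `n_i` is its whole-graph
#' non-neighbor count.  `gamma` controls sharpness: at `gamma = 1` (the
#' default throughout the package) sampling is proportional to `n_i`; as
#' `gamma` grows the distribution concentrates on the candidates with the
#' most non-neighbors and the sampler approaches the deterministic greedy
#' rule.
#'
#' @param counts named numeric vector of non-neighbor counts, as returned by
#'   [non_neighbor_counts()].
#' @param candidates character vector of candidate node labels; each must
#'   appear in `counts` with a strictly positive count (universal nodes are
#'   never candidates).
#' @param gamma positive sharpness exponent.
#' @return Named numeric vector of probabilities over `candidates`, summing
#'   to 1.
#' @examples
#' selection_weights(c(a = 2, b = 1, c = 1, d = 2), c("a", "b", "c", "d"), 1)
#' @export
selection_weights <- function(counts, candidates, gamma = 1) {
  check_gamma(gamma)
  candidates <- as.character(candidates)
  if (!length(candidates)) stop("empty candidate set", call. = FALSE)
  n_i <- counts[candidates]
  if (anyNA(n_i)) {
    stop(sprintf("candidate '%s' has no non-neighbor count",
                 candidates[which(is.na(n_i))[1L]]), call. = FALSE)
  }
  if (any(n_i <= 0)) {
    stop(sprintf("candidate '%s' has zero non-neighbors (universal node)",
                 candidates[which(n_i <= 0)[1L]]), call. = FALSE)
  }
  w <- n_i^gamma
  w <- w / sum(w)
  names(w) <- candidates
  w
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) || gamma <= 0) {
    stop("'gamma' must be a single positive number", call. = FALSE)
  }
  invisible(gamma)
}

# Shared state for one graph: indices of the node classes and global
# non-neighbor counts, computed once per multi-run batch.
sampler_state <- function(graph) {
  n <- n_nodes(graph)
  deg <- graph_degrees(graph)
  isolated <- which(deg == 0L)
  universal <- if (n >= 2L) which(deg == n - 1L) else integer(0)
  regular <- setdiff(seq_len(n), c(isolated, universal))
  list(adj = graph$adjacency, labels = graph$labels, n = n,
       nn = (n - 1L) - deg,            # global non-neighbor counts n_i
       isolated = isolated, regular = regular, universal = universal,
       label_rank = match(graph$labels, sort_labels(graph$labels)))
}

# Core loop over regular-node indices.  `pick` chooses one index from the
# candidate vector given the gamma-powered weights; the stochastic and the
# greedy variants differ only in `pick`.
run_selection_loop <- function(state, pick, gamma) {
  reg <- state$regular
  if (!length(reg)) {
    if (length(state$isolated)) return(state$isolated)
    # all nodes universal (complete graph): no multi-node independent set
    # exists, fall back to the single lexicographically smallest node
    warning("complete graph: every node is adjacent to all others; ",
            "returning a single node", call. = FALSE)
    return(which.min(state$label_rank))
  }
  adj <- state$adj
  w_all <- state$nn[reg]^gamma
  first <- reg[pick(reg, w_all)]
  chosen <- first
  cand <- reg[!adj[first, reg]]
  cand <- cand[cand != first]
  while (length(cand)) {
    k <- cand[pick(cand, state$nn[cand]^gamma)]
    chosen <- c(chosen, k)
    cand <- cand[!adj[k, cand] & cand != k]
  }
  c(state$isolated, chosen)
}

#' Draw one random maximal independent set
#'
#' One pass of the randomized greedy heuristic: a seed node is drawn among
#' the regular nodes with probability proportional to `n_i^gamma`; the
#' candidate set becomes its non-neighbors; then, repeatedly, a node is
#' drawn from the candidate set with the same weights (renormalized over the
#' candidates), added to the growing set, and the candidate set is
#' intersected with the non-neighbors of the drawn node, until no candidate
#' is left.  Isolated nodes are part of every output; universal nodes of
#' none (except on a complete graph, where the single lexicographically
#' smallest node is returned, with a warning).
#'
#' Randomness comes from the current R random number stream; seed it with
#' `set.seed()` or use [run_heuristic()] for seeded multi-run batches.
#'
#' @param graph a [threshold_graph()].
#' @param gamma positive sharpness exponent (see [selection_weights()]).
#' @return Character vector of node labels in canonical (sorted) order; a
#'   maximal independent set of `graph`.
#' @export
sample_maximal_set <- function(graph, gamma = 1) {
  stopifnot(inherits(graph, "threshold_graph"))
  check_gamma(gamma)
  state <- sampler_state(graph)
  sort_labels(state$labels[run_selection_loop(state, pick_random, gamma)])
}

pick_random <- function(cand, w) {
  if (length(cand) == 1L) return(1L)
  sample.int(length(cand), 1L, prob = w)
}

#' Deterministic greedy maximal independent set
#'
#' The `gamma -> Inf` limit of the sampler: at every step the candidate
#' with the largest whole-graph non-neighbor count is taken, ties broken by
#' the lexicographically smallest label.  Deterministic; this is also the
#' pruning rule used by degree-greedy relatedness filters.
#'
#' @param graph a [threshold_graph()].
#' @return Character vector of node labels in canonical (sorted) order; a
#'   maximal independent set of `graph`.
#' @export
greedy_maximal_set <- function(graph) {
  stopifnot(inherits(graph, "threshold_graph"))
  state <- sampler_state(graph)
  rank <- state$label_rank
  pick_greedy <- function(cand, w) {
    best <- which(w == max(w))
    if (length(best) == 1L) return(best)
    best[which.min(rank[cand[best]])]
  }
  sort_labels(state$labels[run_selection_loop(state, pick_greedy, gamma = 1)])
}

#' Repeated randomized runs with de-duplication
#'
#' Runs the deterministic greedy heuristic once and the randomized sampler
#' `runs` times, records every per-run set size, and de-duplicates the
#' collection of maximal independent sets by their canonical (sorted-label)
#' form.  Repeated runs often rediscover the same set; only unique sets are
#' kept.  With the same `seed` the result is exactly reproducible (R's
#' Mersenne-Twister stream; one stream drives the whole batch).
#'
#' @param graph a [threshold_graph()].
#' @param runs number of randomized runs (>= 1).
#' @param seed optional integer seed; `NULL` uses (and advances) the current
#'   random number stream.
#' @param gamma positive sharpness exponent.
#' @return An object of class `indep_run`: a list with
#'   \describe{
#'     \item{unique_sets}{list of unique maximal independent sets (character
#'       vectors, canonical order), sorted by decreasing size then
#'       lexicographically; includes the greedy set.}
#'     \item{greedy_set}{the deterministic greedy result.}
#'     \item{per_run_sizes}{integer vector of the `runs` sampled set sizes.}
#'     \item{gamma, runs, seed}{the configuration.}
#'     \item{n, threshold, connectivity}{graph summary.}
#'   }
#' @examples
#' g <- random_threshold_graph(50, threshold = 0.6, seed = 1)
#' res <- run_heuristic(g, runs = 200, seed = 2)
#' res
#' size_quantiles(res)
#' @export
run_heuristic <- function(graph, runs = 1000L, seed = NULL, gamma = 1) {
  stopifnot(inherits(graph, "threshold_graph"))
  check_gamma(gamma)
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop("'runs' must be >= 1", call. = FALSE)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  state <- sampler_state(graph)

  greedy <- greedy_maximal_set(graph)
  sets <- vector("list", runs + 1L)
  sets[[1L]] <- greedy
  sizes <- integer(runs)
  # a degenerate graph warns identically on every run; say it once
  warned <- character(0)
  withCallingHandlers(
    for (r in seq_len(runs)) {
      s <- sort_labels(state$labels[run_selection_loop(state, pick_random,
                                                       gamma)])
      sizes[r] <- length(s)
      sets[[r + 1L]] <- s
    },
    warning = function(w) {
      msg <- conditionMessage(w)
      if (msg %in% warned) invokeRestart("muffleWarning")
      warned <<- c(warned, msg)
    })

  keys <- vapply(sets, set_key, character(1L))
  uniq <- sets[!duplicated(keys)]
  len <- lengths(uniq)
  uniq <- uniq[order(-len, vapply(uniq, set_key, character(1L)),
                     method = "radix")]

  structure(list(
    unique_sets = uniq,
    greedy_set = greedy,
    per_run_sizes = sizes,
    gamma = gamma, runs = runs,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    n = n_nodes(graph),
    threshold = graph$threshold,
    connectivity = if (n_nodes(graph) >= 2L) connectivity(graph) else NA_real_
  ), class = "indep_run")
}

#' Five-number summary of per-run set sizes
#'
#' Minimum, lower quartile, median, upper quartile and maximum of the sizes
#' of the maximal independent sets found across the randomized runs, using
#' linear interpolation between order statistics (R's default type-7
#' quantiles).
#'
#' @param result an `indep_run` object from [run_heuristic()].
#' @return Named numeric vector `min`, `25%`, `median`, `75%`, `max`.
#' @export
size_quantiles <- function(result) {
  stopifnot(inherits(result, "indep_run"))
  sizes <- result$per_run_sizes
  if (!length(sizes)) stop("no per-run sizes recorded", call. = FALSE)
  q <- stats::quantile(sizes, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  names(q) <- c("min", "25%", "median", "75%", "max")
  q
}

#' @export
print.indep_run <- function(x, ...) {
  cat(sprintf("Randomized independent-set search: %d runs (gamma = %s%s)\n",
              x$runs, format(x$gamma),
              if (is.na(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  cat(sprintf("  graph: %d nodes, threshold %s, connectivity %s\n",
              x$n, format(x$threshold),
              if (is.na(x$connectivity)) "NA" else sprintf("%.4f", x$connectivity)))
  cat(sprintf("  unique maximal independent sets: %d (sizes %d..%d)\n",
              length(x$unique_sets), min(lengths(x$unique_sets)),
              max(lengths(x$unique_sets))))
  cat(sprintf("  greedy set size: %d\n", length(x$greedy_set)))
  q <- size_quantiles(x)
  cat(sprintf("  per-run sizes: min %g | 25%% %g | median %g | 75%% %g | max %g\n",
              q[1L], q[2L], q[3L], q[4L], q[5L]))
  invisible(x)
}

#' @export
summary.indep_run <- function(object, ...) {
  out <- list(runs = object$runs, gamma = object$gamma, seed = object$seed,
              n = object$n, threshold = object$threshold,
              connectivity = object$connectivity,
              n_unique = length(object$unique_sets),
              greedy_size = length(object$greedy_set),
              best_size = max(lengths(object$unique_sets)),
              size_quantiles = size_quantiles(object))
  class(out) <- "summary.indep_run"
  out
}

#' @export
print.summary.indep_run <- function(x, ...) {
  cat(sprintf(
    "%d unique maximal independent sets from %d runs on %d nodes\n",
    x$n_unique, x$runs, x$n))
  cat(sprintf("  best size %d (greedy %d)\n", x$best_size, x$greedy_size))
  q <- x$size_quantiles
  cat(sprintf("  size quantiles: %g / %g / %g / %g / %g\n",
              q[1L], q[2L], q[3L], q[4L], q[5L]))
  invisible(x)
}
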