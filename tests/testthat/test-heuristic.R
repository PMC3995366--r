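test_that("selection weights normalize gamma-powered non-neighbor counts", {
  expect_equal(unname(selection_weights(c(a = 1, b = 1), c("a", "b"))),
               c(0.5, 0.5))
  counts <- c(A = 2, B = 1, C = 1, D = 2)
  w <- selection_weights(counts, c("A", "B", "C", "D"), gamma = 1)
  expect_equal(unname(w), c(1/3, 1/6, 1/6, 1/3))
  expect_equal(sum(w), 1)
  # restriction to a candidate subset renormalizes
  w2 <- selection_weights(counts, c("C", "D"))
  expect_equal(unname(w2), c(1/3, 2/3))
  # large gamma concentrates on the best candidate
  w3 <- selection_weights(c(a = 2, b = 1), c("a", "b"), gamma = 50)
  expect_gt(w3[["a"]], 1 - 1e-14)
  expect_error(selection_weights(counts, character(0)), "empty candidate")
  expect_error(selection_weights(c(a = 0, b = 2), c("a", "b")),
               "universal node")
  expect_error(selection_weights(counts, "nope"), "no non-neighbor count")
  expect_error(selection_weights(counts, "A", gamma = -1), "positive")
})

test_that("sampler output is always a maximal independent set", {
  set.seed(404)
  for (rep in 1:30) {
    n <- sample(5:25, 1L)
    g <- random_threshold_graph(n, threshold = runif(1, 0.1, 0.9),
                                seed = sample.int(1e6, 1L))
    s <- sample_maximal_set(g)
    expect_true(is_independent(g, s))
    expect_true(is_maximal_independent(g, s))
    expect_identical(s, sort(s, method = "radix"))
  }
})

test_that("degenerate graphs are handled explicitly", {
  expect_identical(sample_maximal_set(edgeless_graph(letters[1:4])),
                   letters[1:4])
  expect_warning(s <- sample_maximal_set(complete_graph(c("b", "a", "c"))),
                 "complete graph")
  expect_identical(s, "a")
  # path A-B-C has a single reachable set: B is never drawn first
  g3 <- path_graph(c("A", "B", "C"))
  set.seed(1)
  for (i in 1:50) expect_identical(sample_maximal_set(g3), c("A", "C"))
})

test_that("isolated nodes are in every sampled set, universal nodes in none", {
  labs <- c("iso1", "iso2", "u", "r1", "r2", "r3")
  # u adjacent to every non-isolated node; r1-r2-r3 a path
  g <- graph_from_edges(labs, list(
    c("u", "r1"), c("u", "r2"), c("u", "r3"),
    c("r1", "r2"), c("r2", "r3")))
  # u is universal only among non-isolated nodes, so here it is regular;
  # drop the isolated nodes to make a true universal
  p <- partition_nodes(g)
  expect_setequal(p$isolated, c("iso1", "iso2"))
  set.seed(2)
  for (i in 1:25) {
    s <- sample_maximal_set(g)
    expect_true(all(c("iso1", "iso2") %in% s))
    expect_true(is_maximal_independent(g, s))
  }
  g2 <- graph_from_edges(c("u", "r1", "r2", "r3"), list(
    c("u", "r1"), c("u", "r2"), c("u", "r3"), c("r1", "r2")))
  expect_identical(partition_nodes(g2)$universal, "u")
  set.seed(3)
  for (i in 1:25) expect_false("u" %in% sample_maximal_set(g2))
})

test_that("greedy heuristic is the deterministic largest-count specialization", {
  g <- path_graph(c("A", "B", "C", "D"))
  # ties at n=2 between A and D break to the smaller label, then D follows
  expect_identical(greedy_maximal_set(g), c("A", "D"))
  expect_identical(greedy_maximal_set(edgeless_graph(letters[1:3])),
                   letters[1:3])
  for (seed in 1:20) {
    g <- random_threshold_graph(sample(5:30, 1L), threshold = runif(1),
                                seed = seed)
    s1 <- greedy_maximal_set(g)
    expect_true(is_maximal_independent(g, s1))
    expect_identical(greedy_maximal_set(g), s1)   # deterministic
  }
})

test_that("empirical sampling frequencies match the branch-enumeration law", {
  # two small graphs with non-trivial execution trees
  cases <- list(
    path_graph(c("A", "B", "C", "D")),
    graph_from_edges(c("A", "B", "C", "D", "E"),
                     list(c("A", "B"), c("B", "C"), c("C", "D"),
                          c("D", "E"), c("A", "E")))   # 5-cycle
  )
  n_samp <- 4000L
  set.seed(11)
  for (g in cases) {
    exact <- branch_probabilities(g, gamma = 1)
    draws <- table(vapply(seq_len(n_samp), function(i) {
      paste(sample_maximal_set(g), collapse = " ")
    }, character(1L)))
    expect_setequal(names(draws), names(exact))
    for (key in names(exact)) {
      se <- sqrt(exact[[key]] * (1 - exact[[key]]) / n_samp)
      expect_lt(abs(draws[[key]] / n_samp - exact[[key]]), 4 * se + 1e-12)
    }
  }
})

test_that("large gamma concentrates sampling on greedy-reachable sets", {
  g <- path_graph(c("A", "B", "C", "D"))
  p8 <- branch_probabilities(g, gamma = 8)
  p32 <- branch_probabilities(g, gamma = 32)
  # {A,D} is the greedy outcome; its probability grows toward 1 with gamma
  expect_gt(p8[["A D"]], branch_probabilities(g, gamma = 1)[["A D"]])
  expect_gt(p32[["A D"]], p8[["A D"]])
  expect_gt(p32[["A D"]], 0.999)
  set.seed(5)
  hits <- sum(vapply(1:200, function(i) {
    identical(sample_maximal_set(g, gamma = 32), c("A", "D"))
  }, logical(1L)))
  expect_gt(hits, 195L)
})

test_that("run_heuristic de-duplicates, records sizes and reproduces by seed", {
  g <- path_graph(c("A", "B", "C", "D"))
  res <- run_heuristic(g, runs = 1000, seed = 42)
  expect_s3_class(res, "indep_run")
  # exactly the three maximal sets of the path, largest-first ordering
  expect_identical(set_keys(res$unique_sets), c("A C", "A D", "B D"))
  expect_identical(res$greedy_set, c("A", "D"))
  expect_length(res$per_run_sizes, 1000L)
  expect_gte(max(c(res$per_run_sizes, length(res$greedy_set))),
             length(res$greedy_set))
  res2 <- run_heuristic(g, runs = 1000, seed = 42)
  expect_identical(res2$unique_sets, res$unique_sets)
  expect_identical(res2$per_run_sizes, res$per_run_sizes)
  # every reported set is maximal-independent
  for (s in res$unique_sets) expect_true(is_maximal_independent(g, s))
  expect_error(run_heuristic(g, runs = 0), ">= 1")
})

test_that("unique sets are ordered by decreasing size then lexicographically", {
  g <- random_threshold_graph(25, threshold = 0.6, seed = 8)
  res <- run_heuristic(g, runs = 300, seed = 9)
  len <- lengths(res$unique_sets)
  keys <- set_keys(res$unique_sets)
  expect_false(is.unsorted(rev(len)))
  for (l in unique(len)) {
    k <- keys[len == l]
    expect_identical(k, sort(k, method = "radix"))
  }
  expect_false(anyDuplicated(keys) > 0L)
})

test_that("size quantiles follow the type-7 five-number summary", {
  g <- path_graph(c("A", "B", "C", "D"))
  res <- run_heuristic(g, runs = 50, seed = 1)
  expect_equal(unname(size_quantiles(res)), rep(2, 5))
  res$per_run_sizes <- c(1L, 2L, 3L, 4L, 5L)
  expect_equal(size_quantiles(res),
               c(min = 1, `25%` = 2, median = 3, `75%` = 4, max = 5))
  res$per_run_sizes <- c(1L, 2L, 3L, 10L)
  expect_equal(unname(size_quantiles(res)), c(1, 1.75, 2.5, 4.75, 10))
})
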