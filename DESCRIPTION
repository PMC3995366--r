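Package: indepsel
Title: Randomized Selection of Maximal Independent Sets for Relatedness and
    Linkage Pruning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects large sets of mutually unrelated individuals, or mutually
    unlinked markers, from a symmetric pairwise similarity matrix (kinship,
    coancestry, identity-by-descent, or linkage-disequilibrium r-squared).
    The matrix is thresholded into an undirected graph in which edges join
    related pairs, and maximal independent sets of that graph are sampled with
    a fast randomized greedy heuristic whose sharpness is controlled by a
    gamma exponent; repeated runs yield many distinct maximal sets, reported
    de-duplicated together with the deterministic greedy solution and a
    size-quantile summary. Also provides an exact branch-and-bound maximum
    independent set solver and a Bron-Kerbosch enumerator of all maximal sets
    for small graphs, a generator of random uniform similarity matrices for
    simulation studies, plain-text matrix and result-file input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
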