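# indepsel

Randomized selection of maximal independent sets for pruning related
individuals and linked markers.

## The problem

Genetic analyses — GWAS, conservation programs, population-structure
inference — routinely assume the individuals in the sample are mutually
unrelated, and that the markers in a panel are mutually unlinked.  Large
samples violate both.  Given a symmetric matrix of pairwise similarities
(kinship or coancestry coefficients, IBD sharing, LD r², or any
non-negative measure where larger means more similar) and a user-chosen
threshold, build the undirected, unweighted graph G = (V, E) whose nodes
are the entities and whose edges join pairs with similarity strictly above
the threshold.  A set of mutually unrelated entities is then an
*independent set* of G — a set S ⊆ V with no edge inside it — and
retaining as much data as possible means looking for large *maximal*
independent sets (no further node can be added).  Finding the maximum one
is NP-hard, so beyond a few hundred nodes heuristics are needed.

## The algorithm

`indepsel` implements a stochastic greedy heuristic.  Let nᵢ be the number
of non-neighbors of node i.  Isolated nodes (nᵢ = n−1) belong to every
maximal independent set and are included automatically; universal nodes
(nᵢ = 0) are ignored.  Over the remaining nodes:

1. draw a seed node i with probability pᵢ = nᵢ^γ / Σⱼ nⱼ^γ;
2. set the candidate set to the seed's non-neighbors;
3. repeatedly draw the next node from the candidate set with the same
   weights pᵢ renormalized over the candidates, and intersect the
   candidate set with the drawn node's non-neighbors, until it is empty.

Every run returns a maximal independent set.  The sharpness exponent γ
(default 1) interpolates toward the deterministic greedy rule — always
take the candidate with the largest nᵢ — which is also provided, runs
first, and is included in the output.  Repeating the randomized runs many
times and de-duplicating yields many distinct maximal sets, often some
larger than the greedy one, and reveals whether multiple maximum-size
solutions exist.  An exact branch-and-bound solver (maximum clique on the
complement graph with a greedy-coloring bound) and a Bron–Kerbosch
enumerator of all maximal sets are included for validating the heuristic
on small graphs.

## Input format

A plain-text labeled matrix, whitespace-separated: a header line with the
N entity names, then N rows each holding the row name (same names, same
order) followed by N values.  A 4×4 example, `kinship.txt`:

```
ind1 ind2 ind3 ind4
ind1 1.00 0.62 0.09 0.05
ind2 0.62 1.00 0.58 0.11
ind3 0.09 0.58 1.00 0.71
ind4 0.05 0.11 0.71 1.00
```

Values must be symmetric and non-negative; they may exceed 1.  The
diagonal is ignored.

## Worked example

```r
library(indepsel)
sim <- read_similarity_matrix("kinship.txt")
g   <- threshold_graph(sim, 0.25)   # edge iff similarity > 0.25
g
#> Threshold graph: 4 nodes, 3 edges (threshold 0.25)
#>   connectivity: 0.5000
#>   isolated 0 | regular 4 | universal 0

res <- run_heuristic(g, runs = 1000, seed = 1)
res
#> Randomized independent-set search: 1000 runs (gamma = 1, seed = 1)
#>   graph: 4 nodes, threshold 0.25, connectivity 0.5000
#>   unique maximal independent sets: 3 (sizes 2..2)
#>   greedy set size: 2
#>   per-run sizes: min 2 | 25% 2 | median 2 | 75% 2 | max 2
```

The graph is the path ind1–ind2–ind3–ind4 (edges at 0.62, 0.58, 0.71);
its three maximal independent sets `{ind1, ind3}`, `{ind1, ind4}`,
`{ind2, ind4}` are all found, each listed once however often the runs
rediscovered it.  All three have size 2, so here the greedy answer
(`{ind1, ind4}`) is already maximum — `maximum_independent_set(g)`
confirms the independence number is 2.  `write_result_file(res,
"out.txt")` writes the header (nodes, threshold, connectivity, runs,
seed, gamma), the greedy set flagged as such, one line per unique set
(largest first), and a five-number summary of per-run sizes.

From a shell the same analysis is:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","indepsel.R",package="indepsel"))')" \
  --matrix kinship.txt --threshold 0.25 --runs 1000 --seed 1 \
  --output out.txt --exact --quantiles
```

and `... simulate --n 500 --seed 1 --out sim.txt` writes a random uniform
similarity matrix for experiments.

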