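---
title: "Selecting unrelated individuals and unlinked markers by randomized independent-set search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting unrelated individuals and unlinked markers by randomized independent-set search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indepsel)
```

## The model

The package operates on a labeled symmetric matrix of pairwise
similarities between $n$ entities — individuals scored by kinship,
coancestry or IBD sharing, or markers scored by LD $r^2$.  Any
non-negative measure works, values above 1 included: all that matters is
that larger means more similar, because the analysis is purely ordinal
with respect to a single cut point.  Given a threshold $t \in [0,1]$, the
threshold graph $G$ places an edge between two entities exactly when
their similarity is *strictly* greater than $t$ (a tie at the threshold
is a non-edge).  Unrelatedness of a set of entities is then independence
in $G$, and the object of interest is a large maximal independent set.
We write $n_i$ for the number of non-neighbors of node $i$ and call the
realized edge density $|E| / \binom{n}{2}$ the *connectivity* of the
graph.

Three node classes get special treatment.  Isolated nodes belong to every
maximal independent set, so they are removed from the search and unioned
into every output.  Universal nodes ($n_i = 0$) can only ever form
singleton independent sets, so they are excluded from sampling.  The
heuristic works on the remaining *regular* nodes.

## The randomized greedy sampler

One run draws a seed among the regular nodes with probability
$p_i = n_i^\gamma / \sum_j n_j^\gamma$, initializes the candidate set to
the seed's non-neighbors, then repeatedly draws the next member from the
candidate set with the same weights renormalized over the candidates and
intersects the candidate set with the drawn node's non-neighbors.  When
the candidate set empties, the collected nodes plus the isolated nodes
form a maximal independent set of the full graph — every excluded node
has, by construction, a neighbor inside.

Two deliberate details:

* **Global counts.** The weights always use the whole-graph $n_i$,
  renormalized over the current candidates; they are never recomputed on
  the shrinking subgraph.  The selection rule is defined once, up front,
  and the loop merely restricts it — recomputing would define a different
  (also plausible, but not this) algorithm.
* **Seed choice over regular nodes only.** Isolated nodes are
  pre-included in the output, so letting them be drawn would waste
  iterations as no-ops; the package therefore samples the seed over
  regular nodes only.

The exponent $\gamma > 0$ (default 1) sets how sharply sampling prefers
well-disconnected nodes.  As $\gamma \to \infty$ each draw concentrates
on the candidates with maximal $n_i$ and the sampler degenerates into the
deterministic greedy heuristic, which `greedy_maximal_set()` implements
directly, breaking ties by the lexicographically smallest label (radix,
i.e. C-locale, order — immune to the session locale).  The greedy result
is computed once per batch and always included in the report, so a batch
can never do worse than the deterministic rule.

`run_heuristic()` repeats the sampler `runs` times (default 1000) on one
seeded stream, records every per-run size, and de-duplicates the sets by
their sorted label tuple.  Randomness is R's default Mersenne-Twister
generator; the same seed reproduces the identical result byte for byte on
the same R version, which is what the result-file format is designed to
expose (a `--no-timestamp` mode exists for exactly this comparison).

On a worked instance — the path $A\!-\!B\!-\!C\!-\!D$, where
$n = (2,1,1,2)$ — enumerating every execution branch of the procedure
gives $P(\{A,D\}) = 4/9$ and $P(\{A,C\}) = P(\{B,D\}) = 5/18$ at
$\gamma = 1$.  The test suite freezes these values, re-derives them with
an independent recursive enumeration in the helpers, and checks the
sampler empirically against them at $10^5$ draws.

## Exact references

`maximum_independent_set()` is a deterministic branch and bound, executed
as a maximum clique search on the complement graph: candidates are kept
as bitsets, and the bound is a greedy sequential coloring of the
candidates on the complement — equivalently a greedy clique cover in the
original graph, since a clique can contribute at most one vertex per
color class.  Vertices are pre-ordered with the most non-neighbors first
(label tie-break), which fixes the branching deterministically and feeds
the coloring well.  Any admissible bound preserves exactness; the coloring
bound is an engineering choice.  Node (default 200) and wall-time
(default 60 s) budgets guard against the exponential worst case and
overrun raises a distinct `indepsel_budget_error`.

`enumerate_maximal_sets()` runs Bron–Kerbosch with pivoting on the
complement, producing every maximal independent set exactly once; the
count can grow like $3^{n/3}$, hence its 40-node default budget.  In the
tests both routines are cross-checked against a brute-force sweep of all
$2^n$ subsets on small graphs and against the igraph library's
independence number.

## The simulation harness

`random_similarity_matrix(n, seed)` gives each unordered pair one
independent U(0,1) draw (diagonal fixed at 1, the conventional
self-similarity of coancestry-like measures; it is ignored anyway).
Thresholding at $t$ yields an Erdős–Rényi $G(n, p = 1-t)$ graph, so
expected connectivity is $1 - t$ and threshold plus observed connectivity
is one up to binomial noise — a property the tests verify at
$3\sigma$.

This generator defines the package's study conditions: the calibration
experiments run it at threshold 0.95 for $n = 500, 1000, 2000$ with 1001
heuristic runs each (`scripts/acceptance.R`), and the oracle comparisons
use it at $n \le 20$ (50 graphs across connectivities 0.1–0.9, up to
$2000n$ runs) and $n = 150$ (1500 runs against branch and bound).  Those
sizes keep the full suite under a few minutes while leaving the
statistics sharp; they are the package's own choices.  What uniform
matrices do *not* emulate is the structure of real data: family blocks
(full- and half-sib clusters), heavy-tailed coancestry distributions, LD
decaying along chromosomes, or the huge isolated-node counts of sparse
real cohorts.  Passing tests on $G(n,p)$ graphs therefore validate the
algorithmic machinery, not any claim about a particular population; on
real matrices the size distribution of the discovered sets can look very
different.

## Numerical and format choices

* Matrix files are whitespace-delimited (any run of spaces or tabs);
  symmetry is enforced to an absolute tolerance of $10^{-9}$, generous
  for similarity estimates that rarely carry more than a few significant
  digits, yet tight enough to catch transposition errors, which are
  reported by cell pair.
* Values are serialized with `%.17g`, so write–read–write round trips
  are byte-identical.
* Set size summaries use type-7 quantiles (R's default, linear
  interpolation between order statistics); at 1000+ runs the difference
  between quantile conventions is sub-integer.
* Degenerate inputs are handled explicitly: an edgeless graph returns
  all nodes without sampling; a complete graph has no multi-node
  independent set, so the sampler returns the single lexicographically
  smallest node and warns (once per batch).
* Thresholds are restricted to $[0,1]$; similarities above 1 are legal
  and simply produce edges at every threshold.

## Limitations

The heuristic carries no optimality guarantee; comparisons with the exact
solver in the test suite show the best-of-many-runs attains the true
maximum on small graphs, with any shortfall concentrated at low
connectivity (sparse graphs), where the search space of large independent
sets is widest.  Raising `runs` is the remedy the design offers.  The
sampler is also blind to anything but the graph: phenotype-aware
selection (e.g., preferring affected individuals) and map-aware marker
pruning are out of scope, as is estimating the similarity matrix itself
from genotypes — the package starts where that matrix ends.
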