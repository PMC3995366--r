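#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <ctime>
#include <stdexcept>

// Exact maximum independent set by deterministic branch and bound, run as a
// maximum clique search on the complement graph.  Candidate sets are
// bitsets; the bound is a greedy sequential coloring of the candidates on
// the complement (equivalently a greedy clique cover of the candidates in
// the original graph): a clique can use each color class at most once, so
// vertices are expanded in reverse color order and a branch is cut when
// |R| + color(v) cannot beat the incumbent.  Vertices are pre-ordered in R
// (most non-neighbors first, label tie-break) before reaching this routine,
// which both fixes the branching order deterministically and feeds the
// coloring well.

namespace {

typedef std::vector<uint64_t> bits;

struct Solver {
  int n, nw;
  std::vector<bits> comp;   // complement adjacency rows
  std::vector<int> best;
  std::clock_t t0;
  double max_seconds;
  long checks;

  static void set(bits& b, int i) { b[i >> 6] |= (uint64_t(1) << (i & 63)); }
  static void clear(bits& b, int i) { b[i >> 6] &= ~(uint64_t(1) << (i & 63)); }
  static bool empty(const bits& b) {
    for (size_t w = 0; w < b.size(); ++w) if (b[w]) return false;
    return true;
  }
  static int first(const bits& b) {
    for (size_t w = 0; w < b.size(); ++w) {
      if (b[w]) return (int)(w * 64) + __builtin_ctzll(b[w]);
    }
    return -1;
  }

  void check_budget() {
    if (++checks % 2048 == 0) {
      double el = double(std::clock() - t0) / CLOCKS_PER_SEC;
      if (el > max_seconds) throw std::runtime_error("time budget exceeded");
    }
  }

  void expand(std::vector<int>& R, bits P) {
    check_budget();
    // greedy coloring of P on the complement graph
    std::vector<int> ordered, colors;
    bits uncolored = P;
    int color = 0;
    bits Q(nw);
    while (!empty(uncolored)) {
      ++color;
      Q = uncolored;
      while (!empty(Q)) {
        int v = first(Q);
        clear(Q, v);
        clear(uncolored, v);
        ordered.push_back(v);
        colors.push_back(color);
        for (int w = 0; w < nw; ++w) Q[w] &= ~comp[v][w];
      }
    }
    for (int i = (int)ordered.size() - 1; i >= 0; --i) {
      if ((int)R.size() + colors[i] <= (int)best.size()) return;
      int v = ordered[i];
      bits P2(nw);
      bool p2_empty = true;
      for (int w = 0; w < nw; ++w) {
        P2[w] = P[w] & comp[v][w];
        if (P2[w]) p2_empty = false;
      }
      R.push_back(v);
      if (p2_empty) {
        if (R.size() > best.size()) best = R;
      } else {
        expand(R, P2);
      }
      R.pop_back();
      clear(P, v);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".mis_branch_bound")]]
Rcpp::IntegerVector mis_branch_bound(Rcpp::LogicalMatrix adj,
                                     double max_seconds) {
  int n = adj.nrow();
  Solver s;
  s.n = n;
  s.nw = (n + 63) / 64;
  s.comp.assign(n, bits(s.nw, 0));
  bits P(s.nw, 0);
  for (int i = 0; i < n; ++i) {
    Solver::set(P, i);
    for (int j = 0; j < n; ++j) {
      if (i != j && !adj(i, j)) Solver::set(s.comp[i], j);
    }
  }
  s.t0 = std::clock();
  s.max_seconds = max_seconds;
  s.checks = 0;

  std::vector<int> R;
  try {
    s.expand(R, P);
  } catch (const std::runtime_error&) {
    Rcpp::stop("time budget exceeded");
  }
  Rcpp::IntegerVector out(s.best.size());
  for (size_t i = 0; i < s.best.size(); ++i) out[i] = s.best[i] + 1;
  return out;
}
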