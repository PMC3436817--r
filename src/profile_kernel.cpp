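#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Profile k-mer kernel by depth-first traversal of the k-letter trie.
// Each live triple is (profile index, window start, accumulated cost);
// descending one trie level appends one residue to the k-mer prefix and
// adds the corresponding per-position cost. Triples whose accumulated
// cost reaches sigma are pruned: the cumulative score test (cost < sigma)
// is monotone in depth because costs are non-negative. At depth-k leaves
// the surviving per-profile window counts are multiplied pairwise into
// the Gram matrix.

namespace {

struct Triples {
  std::vector<int> prof;
  std::vector<int> win;
  std::vector<double> cost;
  void push(int p, int w, double c) {
    prof.push_back(p); win.push_back(w); cost.push_back(c);
  }
  size_t size() const { return prof.size(); }
};

// Accumulate leaf counts (profiles arrive sorted by index) and add the
// pairwise products into K. For the symmetric case nb == 0 and K is n x n;
// for the cross case profiles 0..na-1 are rows and na..na+nb-1 columns.
void accumulate_leaf(const Triples& t, NumericMatrix& K, int na, bool cross) {
  std::vector<int> ids;
  std::vector<double> cnt;
  size_t i = 0;
  while (i < t.size()) {
    int p = t.prof[i];
    double c = 0;
    while (i < t.size() && t.prof[i] == p) { c += 1; ++i; }
    ids.push_back(p); cnt.push_back(c);
  }
  if (cross) {
    for (size_t a = 0; a < ids.size(); ++a) {
      if (ids[a] >= na) break;
      for (size_t b = ids.size(); b-- > 0;) {
        if (ids[b] < na) break;
        K(ids[a], ids[b] - na) += cnt[a] * cnt[b];
      }
    }
  } else {
    for (size_t a = 0; a < ids.size(); ++a)
      for (size_t b = a; b < ids.size(); ++b) {
        K(ids[a], ids[b]) += cnt[a] * cnt[b];
        if (b != a) K(ids[b], ids[a]) += cnt[a] * cnt[b];
      }
  }
}

void dfs(const std::vector<NumericMatrix>& costs, const Triples& t,
         int depth, int k, double sigma, NumericMatrix& K, int na,
         bool cross) {
  if (t.size() == 0) return;
  for (int a = 0; a < 20; ++a) {
    Triples child;
    for (size_t i = 0; i < t.size(); ++i) {
      double c = t.cost[i] + costs[t.prof[i]](t.win[i] + depth, a);
      if (c < sigma) child.push(t.prof[i], t.win[i], c);
    }
    if (child.size() == 0) continue;
    if (depth + 1 == k) accumulate_leaf(child, K, na, cross);
    else dfs(costs, child, depth + 1, k, sigma, K, na, cross);
  }
}

Triples root_triples(const std::vector<NumericMatrix>& costs, int k) {
  Triples t;
  for (size_t p = 0; p < costs.size(); ++p) {
    int nwin = costs[p].nrow() - k + 1;
    for (int w = 0; w < nwin; ++w) t.push((int)p, w, 0.0);
  }
  return t;
}

std::vector<NumericMatrix> as_costs(List profiles) {
  std::vector<NumericMatrix> costs;
  costs.reserve(profiles.size());
  for (int i = 0; i < profiles.size(); ++i)
    costs.push_back(as<NumericMatrix>(profiles[i]));
  return costs;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix pk_gram_cpp(List cost_matrices, int k, double sigma) {
  std::vector<NumericMatrix> costs = as_costs(cost_matrices);
  int n = costs.size();
  NumericMatrix K(n, n);
  Triples root = root_triples(costs, k);
  dfs(costs, root, 0, k, sigma, K, 0, false);
  return K;
}

// [[Rcpp::export]]
NumericMatrix pk_cross_cpp(List a_matrices, List b_matrices, int k,
                           double sigma) {
  std::vector<NumericMatrix> costs = as_costs(a_matrices);
  int na = costs.size();
  std::vector<NumericMatrix> bc = as_costs(b_matrices);
  for (size_t i = 0; i < bc.size(); ++i) costs.push_back(bc[i]);
  NumericMatrix K(na, (int)bc.size());
  Triples root = root_triples(costs, k);
  dfs(costs, root, 0, k, sigma, K, na, true);
  return K;
}

// [[Rcpp::export]]
NumericVector pk_self_cpp(List cost_matrices, int k, double sigma) {
  std::vector<NumericMatrix> costs = as_costs(cost_matrices);
  NumericVector out(costs.size());
  for (size_t i = 0; i < costs.size(); ++i) {
    std::vector<NumericMatrix> one(1, costs[i]);
    NumericMatrix K(1, 1);
    Triples root = root_triples(one, k);
    dfs(one, root, 0, k, sigma, K, 0, false);
    out[i] = K(0, 0);
  }
  return out;
}
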