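#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Greedy local moving on a dense (symmetric) modularity matrix B.
// Maximizes sum_ij B(i,j) * delta(g_i, g_j).  Diagonal terms are constant
// under relabeling and do not affect moves.  Nodes are visited in `order`;
// a node moves only for a strictly positive gain (> eps), so ties keep the
// current community (deterministic given the visiting order).
static bool local_move(const NumericMatrix& B, std::vector<int>& memb,
                       const std::vector<int>& order) {
  const int n = B.nrow();
  const double eps = 1e-12;
  bool any = false, improved = true;
  std::vector<double> w(n);
  while (improved) {
    improved = false;
    for (int oi = 0; oi < n; ++oi) {
      const int i = order[oi];
      std::fill(w.begin(), w.end(), 0.0);
      for (int j = 0; j < n; ++j)
        if (j != i) w[memb[j]] += B(i, j);
      const int ci = memb[i];
      double best = w[ci];
      int bestc = ci;
      for (int c = 0; c < n; ++c)
        if (w[c] > best + eps) { best = w[c]; bestc = c; }
      if (bestc != ci) { memb[i] = bestc; improved = true; any = true; }
    }
  }
  return any;
}

// Relabel memberships to 0..K-1 (order of first appearance); returns K.
static int relabel(std::vector<int>& memb) {
  std::vector<int> map(memb.size(), -1);
  int K = 0;
  for (size_t i = 0; i < memb.size(); ++i) {
    if (map[memb[i]] < 0) map[memb[i]] = K++;
    memb[i] = map[memb[i]];
  }
  return K;
}

// [[Rcpp::export]]
List louvain_dense(NumericMatrix B, IntegerVector order1) {
  const int n = B.nrow();
  if (B.ncol() != n) stop("modularity matrix must be square");
  std::vector<int> glob(n);
  for (int i = 0; i < n; ++i) glob[i] = i;

  NumericMatrix cur = clone(B);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = order1[i] - 1;

  while (true) {
    const int m = cur.nrow();
    std::vector<int> memb(m);
    for (int i = 0; i < m; ++i) memb[i] = i;
    local_move(cur, memb, order);
    const int K = relabel(memb);
    if (K == m) break;  // no aggregation possible: converged
    for (int i = 0; i < n; ++i) glob[i] = memb[glob[i]];
    NumericMatrix agg(K, K);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        agg(memb[a], memb[b]) += cur(a, b);
    cur = agg;
    order.resize(K);
    for (int i = 0; i < K; ++i) order[i] = i;
  }

  // objective on the original matrix, diagonal included
  double Q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (glob[i] == glob[j]) Q += B(i, j);

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = glob[i] + 1;
  return List::create(_["membership"] = out, _["Q"] = Q);
}
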