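#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// R = sum_ij G(i,j) c_i c_j for symmetric G with zero diagonal.
static double quality(const NumericMatrix& G, const std::vector<double>& c) {
  const int n = G.nrow();
  double R = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      R += G(i, j) * c[i] * c[j];
  return R;
}

// s_i = sum_j G(i,j) c_j
static void strengths(const NumericMatrix& G, const std::vector<double>& c,
                      std::vector<double>& s) {
  const int n = G.nrow();
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) acc += G(i, j) * c[j];
    s[i] = acc;
  }
}

// Change in R when the coreness values at nodes a and b are swapped:
// dR = 2 (c_b - c_a) * ((s_a - G_ab c_b) - (s_b - G_ab c_a)).
static double swap_delta(const NumericMatrix& G, const std::vector<double>& c,
                         const std::vector<double>& s, int a, int b) {
  const double g = G(a, b);
  return 2.0 * (c[b] - c[a]) * ((s[a] - g * c[b]) - (s[b] - g * c[a]));
}

static void apply_swap(const NumericMatrix& G, std::vector<double>& c,
                       std::vector<double>& s, int a, int b) {
  const int n = G.nrow();
  const double da = c[b] - c[a], db = c[a] - c[b];
  for (int j = 0; j < n; ++j) s[j] += G(j, a) * da + G(j, b) * db;
  std::swap(c[a], c[b]);
}

// Greedy polish: repeatedly apply any strictly improving pair swap.
static double polish(const NumericMatrix& G, std::vector<double>& c,
                     std::vector<double>& s, double R) {
  const int n = G.nrow();
  bool improved = true;
  while (improved) {
    improved = false;
    for (int a = 0; a < n - 1; ++a) {
      for (int b = a + 1; b < n; ++b) {
        const double d = swap_delta(G, c, s, a, b);
        if (d > 1e-12) {
          apply_swap(G, c, s, a, b);
          R += d;
          improved = true;
        }
      }
    }
  }
  return R;
}

// Simulated annealing over assignments of a fixed template vector to nodes.
// init: 1-based permutation giving the starting assignment c[i] = tmpl[init[i]-1].
// Uses R's RNG (seedable with set.seed from the caller).
// [[Rcpp::export]]
List anneal_assignment(NumericMatrix G, NumericVector tmpl, IntegerVector init,
                       double cooling, int stall_sweeps, int max_sweeps,
                       double accept_target) {
  const int n = G.nrow();
  if (tmpl.size() != n || init.size() != n)
    stop("template/init length must match matrix size");

  std::vector<double> c(n), s(n);
  for (int i = 0; i < n; ++i) c[i] = tmpl[init[i] - 1];
  strengths(G, c, s);
  double R = quality(G, c);

  // Calibrate the initial temperature so a typical uphill-cost move is
  // accepted with probability ~accept_target.
  double mean_abs = 0.0;
  int n_probe = std::min(200, n * (n - 1) / 2);
  for (int k = 0; k < n_probe; ++k) {
    int a = (int)(unif_rand() * n), b = (int)(unif_rand() * n);
    if (a == b) { --k; continue; }
    mean_abs += std::fabs(swap_delta(G, c, s, a, b));
  }
  mean_abs /= std::max(1, n_probe);
  double temp = mean_abs > 0 ? -mean_abs / std::log(accept_target) : 1.0;

  std::vector<double> best_c = c;
  double best_R = R;
  const int per_sweep = n * n;
  int stall = 0;

  for (int sweep = 0; sweep < max_sweeps && stall < stall_sweeps; ++sweep) {
    for (int k = 0; k < per_sweep; ++k) {
      int a = (int)(unif_rand() * n), b = (int)(unif_rand() * n);
      if (a == b) continue;
      const double d = swap_delta(G, c, s, a, b);
      if (d > 0 || (temp > 0 && unif_rand() < std::exp(d / temp))) {
        apply_swap(G, c, s, a, b);
        R += d;
        if (R > best_R + 1e-12) { best_R = R; best_c = c; stall = -1; }
      }
    }
    ++stall;
    temp *= cooling;
  }

  c = best_c;
  strengths(G, c, s);
  best_R = polish(G, c, s, quality(G, c));

  return List::create(_["coreness"] = NumericVector(c.begin(), c.end()),
                      _["R"] = best_R);
}
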