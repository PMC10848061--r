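#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Dense all-pairs shortest paths (Floyd-Warshall) on a length matrix.
// Input: N x N matrix of edge lengths, R_PosInf where no edge, diagonal 0.
// Dense connectome matrices (N ~ 90) make the O(N^3) scan the right tool.
// [[Rcpp::export(name = ".fw_distances")]]
NumericMatrix fw_distances(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d(clone(len));
  for (int i = 0; i < n; ++i) d(i, i) = 0.0;
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

static double subgraph_efficiency(const NumericMatrix& w,
                                  const std::vector<int>& idx) {
  int m = (int) idx.size();
  if (m < 2) return 0.0;
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> d((size_t) m * m, inf);
  for (int i = 0; i < m; ++i) {
    d[(size_t) i * m + i] = 0.0;
    for (int j = 0; j < m; ++j) {
      double wij = w(idx[i], idx[j]);
      if (i != j && wij > 0) d[(size_t) i * m + j] = 1.0 / wij;
    }
  }
  for (int k = 0; k < m; ++k)
    for (int i = 0; i < m; ++i) {
      double dik = d[(size_t) i * m + k];
      if (!std::isfinite(dik)) continue;
      for (int j = 0; j < m; ++j) {
        double alt = dik + d[(size_t) k * m + j];
        if (alt < d[(size_t) i * m + j]) d[(size_t) i * m + j] = alt;
      }
    }
  double s = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      if (i != j && std::isfinite(d[(size_t) i * m + j]))
        s += 1.0 / d[(size_t) i * m + j];
  return s / ((double) m * (m - 1));
}

// Local efficiency: mean over nodes of the global efficiency of the subgraph
// induced by each node's neighbours (the node itself excluded), with the
// original weights retained. Nodes with < 2 neighbours contribute 0.
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
double local_efficiency_cpp(NumericMatrix w) {
  int n = w.nrow();
  if (n == 0) return 0.0;
  double total = 0.0;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j)
      if (j != i && w(i, j) > 0) nbr.push_back(j);
    total += subgraph_efficiency(w, nbr);
  }
  return total / n;
}
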