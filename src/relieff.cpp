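#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// ReliefF feature weighting for binary labels.
//
// Attributes are range-normalized over the supplied (training) rows, so
// per-attribute diffs |x_A - y_A| / range_A lie in [0, 1]; zero-range
// (constant) attributes contribute 0 everywhere. Instance distance is
// the Manhattan sum of those normalized diffs. For every evaluated
// instance the k nearest same-class neighbors (hits, self excluded) and
// k nearest other-class neighbors (misses) are found, with distance
// ties broken by row order, and each weight is updated by
// (mean miss diff - mean hit diff) / n_eval, bounding weights in
// [-1, 1].
//
// Internally the matrix is transposed to features-by-samples so the
// per-pair distance loop walks contiguous memory.
//
// [[Rcpp::export]]
NumericVector relieff_weights_cpp(NumericMatrix x, IntegerVector y,
                                  int k_neighbors, IntegerVector eval_idx) {
  const int n = x.nrow(), m = x.ncol();
  const int n_eval = eval_idx.size();

  // range-normalize and transpose: xt[i * m + a] = x(i, a) / range_a
  std::vector<double> xt(static_cast<size_t>(n) * m, 0.0);
  for (int a = 0; a < m; ++a) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double v = x(i, a);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    const double range = hi - lo;
    if (range > 0) {
      const double inv = 1.0 / range;
      for (int i = 0; i < n; ++i)
        xt[static_cast<size_t>(i) * m + a] = x(i, a) * inv;
    } // else leave zeros: constant attribute, diff defined as 0
  }

  NumericVector w(m);
  std::vector<double> dist(n);
  std::vector<int> hits, misses;
  hits.reserve(n); misses.reserve(n);

  for (int e = 0; e < n_eval; ++e) {
    const int i = eval_idx[e] - 1; // 1-based from R
    const double *xi = &xt[static_cast<size_t>(i) * m];
    hits.clear(); misses.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double *xj = &xt[static_cast<size_t>(j) * m];
      double d = 0.0;
      for (int a = 0; a < m; ++a) d += std::fabs(xi[a] - xj[a]);
      dist[j] = d;
      if (y[j] == y[i]) hits.push_back(j); else misses.push_back(j);
    }
    auto by_dist = [&dist](int a, int b) {
      return dist[a] < dist[b] || (dist[a] == dist[b] && a < b);
    };
    const int kh = std::min<int>(k_neighbors, hits.size());
    const int km = std::min<int>(k_neighbors, misses.size());
    std::partial_sort(hits.begin(), hits.begin() + kh, hits.end(), by_dist);
    std::partial_sort(misses.begin(), misses.begin() + km, misses.end(),
                      by_dist);

    const double hit_norm = 1.0 / (static_cast<double>(kh) * n_eval);
    const double miss_norm = 1.0 / (static_cast<double>(km) * n_eval);
    for (int h = 0; h < kh; ++h) {
      const double *xh = &xt[static_cast<size_t>(hits[h]) * m];
      for (int a = 0; a < m; ++a) w[a] -= std::fabs(xi[a] - xh[a]) * hit_norm;
    }
    for (int q = 0; q < km; ++q) {
      const double *xq = &xt[static_cast<size_t>(misses[q]) * m];
      for (int a = 0; a < m; ++a) w[a] += std::fabs(xi[a] - xq[a]) * miss_norm;
    }
  }
  return w;
}
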