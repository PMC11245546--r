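#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// L1 (Manhattan) distances from every row of x to every centroid row.
// [[Rcpp::export]]
NumericMatrix cpp_l1_dist(const NumericMatrix& x, const NumericMatrix& cen) {
  const int n = x.nrow(), d = x.ncol(), k = cen.nrow();
  NumericMatrix out(n, k);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) s += std::fabs(x(i, j) - cen(c, j));
      out(i, c) = s;
    }
  }
  return out;
}

static double col_median(std::vector<double>& v) {
  const size_t n = v.size();
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Batch Lloyd iterations under the Manhattan distance: assign each point to
// the nearest centroid (ties -> lowest index), update each centroid to the
// coordinate-wise median of its members. An emptied cluster is re-seeded at
// the point farthest (L1) from its current centroid. Returns the final
// centroids, 1-based labels, per-point distances, the total-cost trace (cost
// after each assignment step; non-increasing), and the iteration count.
// [[Rcpp::export]]
List cpp_l1_kmeans(const NumericMatrix& x, NumericMatrix cen,
                   int max_iter, double tol) {
  const int n = x.nrow(), d = x.ncol(), k = cen.nrow();
  IntegerVector lab(n);
  NumericVector dist(n);
  std::vector<double> costs;
  double prev_cost = R_PosInf;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    // assignment
    double cost = 0.0;
    for (int i = 0; i < n; ++i) {
      double best = R_PosInf;
      int bestc = 0;
      for (int c = 0; c < k; ++c) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) {
          s += std::fabs(x(i, j) - cen(c, j));
          if (s >= best) break;
        }
        if (s < best) { best = s; bestc = c; }
      }
      lab[i] = bestc + 1;
      dist[i] = best;
      cost += best;
    }
    costs.push_back(cost);

    // empty-cluster repair: re-seed at the globally farthest point
    for (int c = 0; c < k; ++c) {
      int cnt = 0;
      for (int i = 0; i < n; ++i) if (lab[i] == c + 1) ++cnt;
      if (cnt == 0) {
        int far = 0; double fd = -1.0;
        for (int i = 0; i < n; ++i) if (dist[i] > fd) { fd = dist[i]; far = i; }
        for (int j = 0; j < d; ++j) cen(c, j) = x(far, j);
        lab[far] = c + 1;
        dist[far] = 0.0;
      }
    }

    if (prev_cost - cost <= tol) break;
    prev_cost = cost;

    // update: coordinate-wise median per cluster
    for (int c = 0; c < k; ++c) {
      std::vector<int> members;
      for (int i = 0; i < n; ++i) if (lab[i] == c + 1) members.push_back(i);
      if (members.empty()) continue;
      std::vector<double> col(members.size());
      for (int j = 0; j < d; ++j) {
        for (size_t m = 0; m < members.size(); ++m) col[m] = x(members[m], j);
        cen(c, j) = col_median(col);
      }
    }
  }

  return List::create(_["centroids"] = cen, _["labels"] = lab,
                      _["distances"] = dist, _["cost_trace"] = wrap(costs),
                      _["iterations"] = std::min(it, max_iter));
}

// Sample a discrete-time Markov chain. p0: initial distribution, trans: row-
// stochastic matrix, u: uniforms (length n, u[0] picks the initial state).
// [[Rcpp::export]]
IntegerVector cpp_markov_sample(const NumericVector& p0,
                                const NumericMatrix& trans,
                                const NumericVector& u) {
  const int n = u.size(), k = p0.size();
  IntegerVector s(n);
  double acc = 0.0;
  int cur = k - 1;
  for (int c = 0; c < k; ++c) { acc += p0[c]; if (u[0] <= acc) { cur = c; break; } }
  s[0] = cur + 1;
  for (int t = 1; t < n; ++t) {
    acc = 0.0;
    int nxt = k - 1;
    for (int c = 0; c < k; ++c) { acc += trans(cur, c); if (u[t] <= acc) { nxt = c; break; } }
    cur = nxt;
    s[t] = cur + 1;
  }
  return s;
}
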