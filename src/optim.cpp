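// Post-growth global relaxation: synchronous nearest-neighbour
// attraction/repulsion sweeps over all skeleton points.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct CellGrid {
  double lo[3], cell;
  int dims[3];
  std::vector<std::vector<int>> cells;

  void build(const std::vector<double>& P, int n, double cell_) {
    cell = cell_;
    double mn[3] = {1e30, 1e30, 1e30}, mx[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        mn[k] = std::min(mn[k], P[3 * (size_t)i + k]);
        mx[k] = std::max(mx[k], P[3 * (size_t)i + k]);
      }
    for (int k = 0; k < 3; ++k) {
      lo[k] = mn[k] - cell;
      dims[k] = std::max(1, (int)std::ceil((mx[k] - lo[k]) / cell) + 2);
    }
    cells.assign((size_t)dims[0] * dims[1] * dims[2], {});
    for (int i = 0; i < n; ++i) {
      int c[3];
      for (int k = 0; k < 3; ++k)
        c[k] = std::min(dims[k] - 1,
                        std::max(0, (int)std::floor((P[3 * (size_t)i + k] - lo[k]) / cell)));
      cells[((size_t)c[2] * dims[1] + c[1]) * dims[0] + c[0]].push_back(i);
    }
  }

  template <class F>
  void ring(const double* p, int radius_cells, F&& fn) const {
    int c[3];
    for (int k = 0; k < 3; ++k)
      c[k] = std::min(dims[k] - 1,
                      std::max(0, (int)std::floor((p[k] - lo[k]) / cell)));
    for (int kz = std::max(0, c[2] - radius_cells);
         kz <= std::min(dims[2] - 1, c[2] + radius_cells); ++kz)
      for (int ky = std::max(0, c[1] - radius_cells);
           ky <= std::min(dims[1] - 1, c[1] + radius_cells); ++ky)
        for (int kx = std::max(0, c[0] - radius_cells);
             kx <= std::min(dims[0] - 1, c[0] + radius_cells); ++kx)
          for (int id : cells[((size_t)kz * dims[1] + ky) * dims[0] + kx]) fn(id);
  }
};

}  // namespace

// [[Rcpp::export]]
List global_optimise_cpp(NumericMatrix P0, NumericVector r, IntegerVector fid,
                         LogicalVector movable, int n_nb, int max_iter,
                         double tol, double step_frac) {
  int n = P0.nrow();
  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * (size_t)i + k] = P0(i, k);

  double mean_r = 0;
  for (int i = 0; i < n; ++i) mean_r += r[i];
  mean_r = n > 0 ? mean_r / n : 1.0;
  double cell = std::max(3.0 * mean_r, 1e-3);

  std::vector<double> best = P;
  double best_overlap = R_PosInf;
  std::vector<double> trace;
  std::vector<double> U(3 * (size_t)n);
  std::vector<std::pair<double, int>> cand;

  int since_best = 0;
  const int patience = 10;  // sweeps without a new best before stopping
  for (int iter = 0; iter < max_iter; ++iter) {
    CellGrid g;
    g.build(P, n, cell);
    double overlap = 0;
    std::fill(U.begin(), U.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double* pi = &P[3 * (size_t)i];
      cand.clear();
      int ring = 1;
      while ((int)cand.size() < n_nb && ring <= std::max({g.dims[0], g.dims[1], g.dims[2]})) {
        cand.clear();
        g.ring(pi, ring, [&](int j) {
          if (fid[j] == fid[i]) return;
          const double* pj = &P[3 * (size_t)j];
          double d2 = 0;
          for (int k = 0; k < 3; ++k) d2 += (pi[k] - pj[k]) * (pi[k] - pj[k]);
          cand.emplace_back(d2, j);
        });
        ++ring;
      }
      int m = std::min((int)cand.size(), n_nb);
      if (m == 0) continue;
      std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
      double u[3] = {0, 0, 0};
      for (int s = 0; s < m; ++s) {
        int j = cand[s].second;
        const double* pj = &P[3 * (size_t)j];
        double d = std::sqrt(cand[s].first);
        double target = r[i] + r[j];
        overlap += std::max(0.0, target - d);
        double sgn = (target - d > 0) ? 1.0 : (target - d < 0 ? -1.0 : 0.0);
        if (d < 1e-12) {
          // coincident points: seeded random jitter
          double jv[3] = {norm_rand(), norm_rand(), norm_rand()};
          double jn = std::sqrt(jv[0] * jv[0] + jv[1] * jv[1] + jv[2] * jv[2]);
          for (int k = 0; k < 3; ++k) u[k] += 1e-3 * r[i] * jv[k] / std::max(jn, 1e-12);
        } else {
          for (int k = 0; k < 3; ++k) u[k] += sgn * (pi[k] - pj[k]);
        }
      }
      double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      double cap = step_frac * r[i];
      if (un > cap && un > 0)
        for (int k = 0; k < 3; ++k) u[k] *= cap / un;
      if (movable[i])
        for (int k = 0; k < 3; ++k) U[3 * (size_t)i + k] = u[k];
    }
    trace.push_back(overlap);
    if (overlap < best_overlap * (1.0 - tol) || !std::isfinite(best_overlap)) {
      best_overlap = std::min(best_overlap, overlap);
      best = P;
      since_best = 0;
    } else {
      if (overlap < best_overlap) { best_overlap = overlap; best = P; }
      ++since_best;
    }
    if (overlap <= 1e-12) break;
    // the literal update oscillates at the step cap once contacts form, so
    // the sweep loop stops when the metric has not improved (relative tol)
    // for `patience` consecutive sweeps; the best state is returned
    if (since_best >= patience) break;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) P[3 * (size_t)i + k] += U[3 * (size_t)i + k];
  }

  NumericMatrix Pout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Pout(i, k) = best[3 * (size_t)i + k];
  return List::create(_["positions"] = Pout, _["trace"] = wrap(trace),
                      _["overlap"] = best_overlap);
}

// [[Rcpp::export]]
double overlap_metric_cpp(NumericMatrix P0, NumericVector r, IntegerVector fid,
                          int n_nb) {
  int n = P0.nrow();
  std::vector<double> P(3 * (size_t)n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) P[3 * (size_t)i + k] = P0(i, k);
  double mean_r = 0;
  for (int i = 0; i < n; ++i) mean_r += r[i];
  mean_r = n > 0 ? mean_r / n : 1.0;
  CellGrid g;
  g.build(P, n, std::max(3.0 * mean_r, 1e-3));
  double overlap = 0;
  std::vector<std::pair<double, int>> cand;
  for (int i = 0; i < n; ++i) {
    const double* pi = &P[3 * (size_t)i];
    cand.clear();
    int ring = 1;
    while ((int)cand.size() < n_nb && ring <= std::max({g.dims[0], g.dims[1], g.dims[2]})) {
      cand.clear();
      g.ring(pi, ring, [&](int j) {
        if (fid[j] == fid[i]) return;
        const double* pj = &P[3 * (size_t)j];
        double d2 = 0;
        for (int k = 0; k < 3; ++k) d2 += (pi[k] - pj[k]) * (pi[k] - pj[k]);
        cand.emplace_back(d2, j);
      });
      ++ring;
    }
    int m = std::min((int)cand.size(), n_nb);
    std::partial_sort(cand.begin(), cand.begin() + m, cand.end());
    for (int s = 0; s < m; ++s)
      overlap += std::max(0.0, r[i] + r[cand[s].second] - std::sqrt(cand[s].first));
  }
  return overlap;
}
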