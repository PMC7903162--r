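// 2D circle packing relaxation: pairwise repulsion with gradual radius
// inflation (Lubachevsky-Stillinger style), grid-accelerated.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
List pack_relax_cpp(NumericVector x0, NumericVector y0, NumericVector r,
                    double W, double H, int n_scales, int sweeps_per_scale,
                    int final_sweeps, double push) {
  int n = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  double rmax = 0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, r[i]);
  double cell = std::max(2.2 * rmax, 1e-6);
  int nx = std::max(1, (int)std::ceil(W / cell));
  int ny = std::max(1, (int)std::ceil(H / cell));
  std::vector<std::vector<int>> grid((size_t)nx * ny);

  auto rebuild = [&]() {
    for (auto& g : grid) g.clear();
    for (int i = 0; i < n; ++i) {
      int ci = std::min(nx - 1, std::max(0, (int)(x[i] / cell)));
      int cj = std::min(ny - 1, std::max(0, (int)(y[i] / cell)));
      grid[(size_t)cj * nx + ci].push_back(i);
    }
  };

  int overlaps = 0;
  auto sweep_once = [&](double s) -> int {
    rebuild();
    int n_overlap = 0;
    for (int i = 0; i < n; ++i) {
      int ci = std::min(nx - 1, std::max(0, (int)(x[i] / cell)));
      int cj = std::min(ny - 1, std::max(0, (int)(y[i] / cell)));
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = ci + di, jj = cj + dj;
          if (ii < 0 || jj < 0 || ii >= nx || jj >= ny) continue;
          for (int j : grid[(size_t)jj * nx + ii]) {
            if (j <= i) continue;
            double dx = x[i] - x[j], dy = y[i] - y[j];
            double d2 = dx * dx + dy * dy;
            double tgt = s * (r[i] + r[j]);
            if (d2 >= tgt * tgt) continue;
            double d = std::sqrt(d2);
            if (tgt - d > 1e-9) ++n_overlap;  // ignore contact-level residuals
            double gap = tgt - d;
            double ux, uy;
            if (d < 1e-9) {
              double ang = unif_rand() * 6.283185307179586;
              ux = std::cos(ang);
              uy = std::sin(ang);
            } else {
              ux = dx / d;
              uy = dy / d;
            }
            double m = push * gap * 0.5;
            x[i] += ux * m; y[i] += uy * m;
            x[j] -= ux * m; y[j] -= uy * m;
          }
        }
      double ri = s * r[i];
      x[i] = std::min(std::max(x[i], ri), W - ri);
      y[i] = std::min(std::max(y[i], ri), H - ri);
    }
    return n_overlap;
  };

  for (int sc = 0; sc < n_scales; ++sc) {
    double s = 0.5 + 0.5 * (sc + 1.0) / n_scales;
    for (int k = 0; k < sweeps_per_scale; ++k) {
      if (sweep_once(s) == 0) break;
    }
  }
  overlaps = 0;
  for (int k = 0; k < final_sweeps; ++k) {
    overlaps = sweep_once(1.0);
    if (overlaps == 0) break;
  }
  return List::create(_["x"] = wrap(x), _["y"] = wrap(y),
                      _["overlaps"] = overlaps);
}
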