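// Growth-network engine: Delaunay-connected node cloud with per-node
// occupancy state (max sustainable diameter dc, nearest bundle bc) and
// capsule-chain clearance queries against the fibres grown so far.
#include <Rcpp.h>
#include "delaunay.h"

using namespace Rcpp;
using fphant::Delaunay3;

namespace {

struct Seg {
  double a[3], b[3], ra, rb;
  int bundle;
};

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// distance from point to capsule segment surface (negative = inside)
inline double seg_clearance(const double* p, const Seg& s) {
  double ab[3] = {s.b[0] - s.a[0], s.b[1] - s.a[1], s.b[2] - s.a[2]};
  double ap[3] = {p[0] - s.a[0], p[1] - s.a[1], p[2] - s.a[2]};
  double L2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = L2 > 0 ? clampd((ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / L2, 0.0, 1.0) : 0.0;
  double dx = ap[0] - t * ab[0], dy = ap[1] - t * ab[1], dz = ap[2] - t * ab[2];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  return d - (s.ra + t * (s.rb - s.ra));
}

struct UniformGrid {
  double lo[3], cell;
  int dims[3];
  std::vector<std::vector<int>> cells;

  void init(const double* lo_, const double* hi_, double cell_) {
    cell = cell_;
    for (int k = 0; k < 3; ++k) {
      lo[k] = lo_[k];
      dims[k] = std::max(1, (int)std::ceil((hi_[k] - lo_[k]) / cell));
    }
    cells.assign((size_t)dims[0] * dims[1] * dims[2], {});
  }
  inline int idx(int i, int j, int k) const {
    return (k * dims[1] + j) * dims[0] + i;
  }
  inline void coord(const double* p, int* out) const {
    for (int k = 0; k < 3; ++k)
      out[k] = (int)clampd(std::floor((p[k] - lo[k]) / cell), 0.0, dims[k] - 1.0);
  }
  void add_point(const double* p, int id) {
    int c[3];
    coord(p, c);
    cells[idx(c[0], c[1], c[2])].push_back(id);
  }
  void add_aabb(const double* mn, const double* mx, int id) {
    int c0[3], c1[3];
    coord(mn, c0);
    coord(mx, c1);
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          cells[idx(i, j, k)].push_back(id);
  }
  template <class F>
  void for_aabb(const double* mn, const double* mx, F&& fn) const {
    int c0[3], c1[3];
    coord(mn, c0);
    coord(mx, c1);
    for (int k = c0[2]; k <= c1[2]; ++k)
      for (int j = c0[1]; j <= c1[1]; ++j)
        for (int i = c0[0]; i <= c1[0]; ++i)
          for (int id : cells[idx(i, j, k)]) fn(id);
  }
};

class GrowthEngine {
 public:
  Delaunay3 tri;
  double lo[3], hi[3];
  double track_radius;
  std::vector<double> dc;       // diameter, INFINITY = no fibre within cutoff
  std::vector<int> bc;          // 0 = none
  std::vector<char> occupied;
  std::vector<Seg> segs;
  UniformGrid node_grid, seg_grid;
  std::vector<int> stamp;
  int cur_stamp = 0;

  GrowthEngine(const NumericMatrix& pts, NumericVector lo_, NumericVector hi_,
               double track_radius_, double grid_cell) {
    track_radius = track_radius_;
    for (int k = 0; k < 3; ++k) { lo[k] = lo_[k]; hi[k] = hi_[k]; }
    tri.init(lo, hi);
    int n = pts.nrow();
    std::vector<double> xyz(3 * (size_t)n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) xyz[3 * (size_t)i + k] = pts(i, k);
    tri.insert_points(xyz);
    dc.assign(n, INFINITY);
    bc.assign(n, 0);
    occupied.assign(n, 0);
    stamp.assign(n, 0);
    node_grid.init(lo, hi, grid_cell);
    seg_grid.init(lo, hi, grid_cell);
    for (int i = 0; i < n; ++i) node_grid.add_point(&xyz[3 * (size_t)i], i);
  }

  int n_nodes() const { return tri.n_real(); }
  const double* node_pos(int i) const { return tri.P(tri.n_aux + i); }

  // clearance of arbitrary point to all stored fibres (exact, grid-assisted)
  double clearance_at(const double* p, int* bundle_out) const {
    double best = INFINITY;
    int bb = 0;
    double mn[3], mx[3];
    for (int k = 0; k < 3; ++k) {
      mn[k] = p[k] - track_radius;
      mx[k] = p[k] + track_radius;
    }
    // segments are registered with their radius-expanded AABB
    std::vector<char> seen(segs.size() ? segs.size() : 1, 0);
    seg_grid.for_aabb(mn, mx, [&](int id) {
      if (seen[id]) return;
      seen[id] = 1;
      double c = seg_clearance(p, segs[id]);
      if (c < best) { best = c; bb = segs[id].bundle; }
    });
    if (bundle_out) *bundle_out = bb;
    return best;
  }

  void update_fibre(const NumericMatrix& skel, int bundle) {
    int m = skel.nrow();
    std::vector<int> fibre_segs;
    for (int k = 0; k + 1 < m; ++k) {
      Seg s;
      for (int d = 0; d < 3; ++d) { s.a[d] = skel(k, d); s.b[d] = skel(k + 1, d); }
      s.ra = skel(k, 3);
      s.rb = skel(k + 1, 3);
      s.bundle = bundle;
      int id = (int)segs.size();
      segs.push_back(s);
      fibre_segs.push_back(id);
      double mn[3], mx[3], r = std::max(s.ra, s.rb);
      for (int d = 0; d < 3; ++d) {
        mn[d] = std::min(s.a[d], s.b[d]) - r;
        mx[d] = std::max(s.a[d], s.b[d]) + r;
      }
      seg_grid.add_aabb(mn, mx, id);
    }
    // gather candidate nodes once (stamped), then exact min over the
    // fibre's segments
    ++cur_stamp;
    std::vector<int> cand;
    for (int id : fibre_segs) {
      const Seg& s = segs[id];
      double r = std::max(s.ra, s.rb) + track_radius;
      double mn[3], mx[3];
      for (int d = 0; d < 3; ++d) {
        mn[d] = std::min(s.a[d], s.b[d]) - r;
        mx[d] = std::max(s.a[d], s.b[d]) + r;
      }
      node_grid.for_aabb(mn, mx, [&](int nid) {
        if (stamp[nid] != cur_stamp) {
          stamp[nid] = cur_stamp;
          cand.push_back(nid);
        }
      });
    }
    for (int nid : cand) {
      const double* p = node_pos(nid);
      double best = INFINITY;
      for (int id : fibre_segs) {
        double c = seg_clearance(p, segs[id]);
        if (c < best) best = c;
      }
      if (best > track_radius) continue;
      if (best <= 0) {
        occupied[nid] = 1;
        dc[nid] = 0;
        bc[nid] = bundle;
      } else if (2 * best < dc[nid]) {
        dc[nid] = 2 * best;
        bc[nid] = bundle;
      }
    }
  }

  IntegerVector add_nodes(const NumericMatrix& pts) {
    int n = pts.nrow();
    std::vector<double> xyz(3 * (size_t)n);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) xyz[3 * (size_t)i + k] = pts(i, k);
    int first_vid = tri.insert_points(xyz);
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
      const double* p = &xyz[3 * (size_t)i];
      int bb = 0;
      double c = clearance_at(p, &bb);
      double d = c <= 0 ? 0.0 : (c > track_radius ? INFINITY : 2 * c);
      dc.push_back(d);
      bc.push_back(std::isinf(d) ? 0 : bb);
      occupied.push_back(c <= 0 ? 1 : 0);
      stamp.push_back(0);
      node_grid.add_point(p, first_vid - tri.n_aux + i);
      out[i] = first_vid - tri.n_aux + i + 1;  // 1-based node index
    }
    return out;
  }
};

}  // namespace

// [[Rcpp::export]]
SEXP ge_new(NumericMatrix points, NumericVector lo, NumericVector hi,
            double track_radius, double grid_cell) {
  XPtr<GrowthEngine> p(new GrowthEngine(points, lo, hi, track_radius, grid_cell),
                       true);
  return p;
}

// [[Rcpp::export]]
int ge_n_nodes(SEXP ptr) {
  XPtr<GrowthEngine> p(ptr);
  return p->n_nodes();
}

// [[Rcpp::export]]
NumericMatrix ge_positions(SEXP ptr, IntegerVector idx) {
  XPtr<GrowthEngine> p(ptr);
  NumericMatrix out(idx.size(), 3);
  for (int i = 0; i < idx.size(); ++i) {
    const double* q = p->node_pos(idx[i] - 1);
    for (int k = 0; k < 3; ++k) out(i, k) = q[k];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector ge_neighbours(SEXP ptr, int i) {
  XPtr<GrowthEngine> p(ptr);
  std::vector<int> nb;
  p->tri.vertex_neighbours(p->tri.n_aux + i - 1, nb);
  std::vector<int> real;
  for (int v : nb)
    if (v >= p->tri.n_aux) real.push_back(v - p->tri.n_aux + 1);
  std::sort(real.begin(), real.end());
  return wrap(real);
}

// [[Rcpp::export]]
List ge_state(SEXP ptr, IntegerVector idx) {
  XPtr<GrowthEngine> p(ptr);
  int n = idx.size();
  NumericVector dc(n);
  IntegerVector bc(n);
  LogicalVector occ(n);
  for (int i = 0; i < n; ++i) {
    int j = idx[i] - 1;
    dc[i] = p->dc[j];
    bc[i] = p->bc[j];
    occ[i] = p->occupied[j] != 0;
  }
  return List::create(_["dc"] = dc, _["bc"] = bc, _["occupied"] = occ);
}

// [[Rcpp::export]]
void ge_update_fibre(SEXP ptr, NumericMatrix skel, int bundle) {
  XPtr<GrowthEngine> p(ptr);
  if (skel.nrow() < 2) stop("fibre skeleton needs at least 2 points");
  p->update_fibre(skel, bundle);
}

// [[Rcpp::export]]
IntegerVector ge_add_nodes(SEXP ptr, NumericMatrix pts) {
  XPtr<GrowthEngine> p(ptr);
  if (pts.nrow() == 0) return IntegerVector(0);
  return p->add_nodes(pts);
}

// [[Rcpp::export]]
NumericVector ge_clearance(SEXP ptr, NumericMatrix pts) {
  // exact clearance to all stored fibre capsules (brute force; for audits)
  XPtr<GrowthEngine> p(ptr);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = INFINITY;
    for (const auto& s : p->segs) best = std::min(best, seg_clearance(q, s));
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
int ge_nearest_node(SEXP ptr, NumericVector x, bool accessible_only) {
  XPtr<GrowthEngine> p(ptr);
  double q[3] = {x[0], x[1], x[2]};
  int best = -1;
  double bd = INFINITY;
  // expanding grid search around the query point
  for (double R = 2 * p->node_grid.cell; best < 0 && R < 1e6; R *= 2) {
    double mn[3] = {q[0] - R, q[1] - R, q[2] - R};
    double mx[3] = {q[0] + R, q[1] + R, q[2] + R};
    p->node_grid.for_aabb(mn, mx, [&](int id) {
      if (accessible_only && p->occupied[id]) return;
      const double* pp = p->node_pos(id);
      double d = 0;
      for (int k = 0; k < 3; ++k) d += (pp[k] - q[k]) * (pp[k] - q[k]);
      if (d < bd) { bd = d; best = id; }
    });
  }
  return best + 1;
}

// [[Rcpp::export]]
IntegerMatrix ge_edges(SEXP ptr) {
  XPtr<GrowthEngine> p(ptr);
  std::vector<std::pair<int, int>> e;
  p->tri.real_edges(e);
  IntegerMatrix out((int)e.size(), 2);
  for (size_t i = 0; i < e.size(); ++i) {
    out(i, 0) = e[i].first - p->tri.n_aux + 1;
    out(i, 1) = e[i].second - p->tri.n_aux + 1;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector ge_edge_lengths_sample(SEXP ptr, int n_sample) {
  // lengths of Delaunay edges incident to n_sample evenly spaced nodes
  XPtr<GrowthEngine> p(ptr);
  int n = p->n_nodes();
  std::vector<double> lens;
  int step = std::max(1, n / std::max(1, n_sample));
  std::vector<int> nb;
  for (int i = 0; i < n; i += step) {
    p->tri.vertex_neighbours(p->tri.n_aux + i, nb);
    const double* a = p->node_pos(i);
    for (int v : nb) {
      if (v < p->tri.n_aux) continue;
      const double* b = p->tri.P(v);
      double d = 0;
      for (int k = 0; k < 3; ++k) d += (a[k] - b[k]) * (a[k] - b[k]);
      lens.push_back(std::sqrt(d));
    }
  }
  return wrap(lens);
}

// [[Rcpp::export]]
int ge_count_tets(SEXP ptr) {
  XPtr<GrowthEngine> p(ptr);
  int n = 0;
  for (const auto& t : p->tri.tets)
    if (t.alive) ++n;
  return n;
}

// [[Rcpp::export]]
List ge_tets(SEXP ptr) {
  // alive tetrahedra on real vertices only (for small-instance oracles)
  XPtr<GrowthEngine> p(ptr);
  std::vector<std::array<int, 4>> keep;
  for (const auto& t : p->tri.tets) {
    if (!t.alive) continue;
    bool real = true;
    for (int i = 0; i < 4; ++i)
      if (t.v[i] < p->tri.n_aux) real = false;
    if (!real) continue;
    keep.push_back({t.v[0] - p->tri.n_aux + 1, t.v[1] - p->tri.n_aux + 1,
                    t.v[2] - p->tri.n_aux + 1, t.v[3] - p->tri.n_aux + 1});
  }
  IntegerMatrix out((int)keep.size(), 4);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int k = 0; k < 4; ++k) out(i, k) = keep[i][k];
  return List::create(_["tets"] = out);
}

// [[Rcpp::export]]
NumericVector capsule_min_distance(NumericMatrix pts, NumericMatrix skel) {
  // distance from points to a capsule chain surface (negative = inside)
  int m = skel.nrow();
  std::vector<Seg> ss;
  for (int k = 0; k + 1 < m; ++k) {
    Seg s;
    for (int d = 0; d < 3; ++d) { s.a[d] = skel(k, d); s.b[d] = skel(k + 1, d); }
    s.ra = skel(k, 3);
    s.rb = skel(k + 1, 3);
    s.bundle = 0;
    ss.push_back(s);
  }
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double best = INFINITY;
    for (const auto& s : ss) best = std::min(best, seg_clearance(q, s));
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector capsules_density_grid(List skels, NumericVector roi_lo,
                                    NumericVector roi_hi, double voxel) {
  // fraction of voxel centres inside the union of capsule chains
  std::vector<Seg> ss;
  for (int f = 0; f < skels.size(); ++f) {
    NumericMatrix skel = skels[f];
    for (int k = 0; k + 1 < skel.nrow(); ++k) {
      Seg s;
      for (int d = 0; d < 3; ++d) { s.a[d] = skel(k, d); s.b[d] = skel(k + 1, d); }
      s.ra = skel(k, 3);
      s.rb = skel(k + 1, 3);
      s.bundle = 0;
      ss.push_back(s);
    }
  }
  double lo[3] = {roi_lo[0], roi_lo[1], roi_lo[2]};
  double hi[3] = {roi_hi[0], roi_hi[1], roi_hi[2]};
  UniformGrid g;
  double cell = std::max(voxel * 4, 1.0);
  g.init(lo, hi, cell);
  for (size_t id = 0; id < ss.size(); ++id) {
    const Seg& s = ss[id];
    double r = std::max(s.ra, s.rb);
    double mn[3], mx[3];
    for (int d = 0; d < 3; ++d) {
      mn[d] = clampd(std::min(s.a[d], s.b[d]) - r, lo[d], hi[d]);
      mx[d] = clampd(std::max(s.a[d], s.b[d]) + r, lo[d], hi[d]);
    }
    g.add_aabb(mn, mx, (int)id);
  }
  int nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / voxel));
  int ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / voxel));
  int nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / voxel));
  long long inside = 0, total = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double q[3] = {lo[0] + (i + 0.5) * voxel, lo[1] + (j + 0.5) * voxel,
                       lo[2] + (k + 0.5) * voxel};
        ++total;
        bool in = false;
        g.for_aabb(q, q, [&](int id) {
          if (!in && seg_clearance(q, ss[id]) <= 0) in = true;
        });
        if (in) ++inside;
      }
  NumericVector out(2);
  out[0] = total > 0 ? (double)inside / (double)total : 0.0;
  out[1] = (double)total;
  return out;
}
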