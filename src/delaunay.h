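// Incremental 3D Delaunay triangulation (Bowyer-Watson with visibility walk).
// Supports batched incremental insertion so the growth network can be
// densified after each fibre without a full rebuild.
#pragma once

#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <stdexcept>
#include <algorithm>

namespace fphant {

struct Tet {
  int v[4];   // vertex ids
  int nb[4];  // nb[i] = tet opposite vertex v[i], -1 at hull
  bool alive;
};

// determinant of (a-d, b-d, c-d); positive orientation convention
inline long double orient3d(const double* a, const double* b, const double* c,
                            const double* d) {
  long double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  long double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  long double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

// >0 iff p strictly inside circumsphere of positively oriented (a,b,c,d)
inline long double insphere(const double* a, const double* b, const double* c,
                            const double* d, const double* p) {
  long double aex = a[0] - p[0], aey = a[1] - p[1], aez = a[2] - p[2];
  long double bex = b[0] - p[0], bey = b[1] - p[1], bez = b[2] - p[2];
  long double cex = c[0] - p[0], cey = c[1] - p[1], cez = c[2] - p[2];
  long double dex = d[0] - p[0], dey = d[1] - p[1], dez = d[2] - p[2];
  long double ae2 = aex * aex + aey * aey + aez * aez;
  long double be2 = bex * bex + bey * bey + bez * bez;
  long double ce2 = cex * cex + cey * cey + cez * cez;
  long double de2 = dex * dex + dey * dey + dez * dez;
  long double ab = aex * bey - bex * aey;
  long double ac = aex * cey - cex * aey;
  long double ad = aex * dey - dex * aey;
  long double bc = bex * cey - cex * bey;
  long double bd = bex * dey - dex * bey;
  long double cd = cex * dey - dex * cey;
  long double abc = aez * bc - bez * ac + cez * ab;
  long double abd = aez * bd - bez * ad + dez * ab;
  long double acd = aez * cd - cez * ad + dez * ac;
  long double bcd = bez * cd - cez * bd + dez * bc;
  return de2 * abc - ce2 * abd + be2 * acd - ae2 * bcd;
}

class Delaunay3 {
 public:
  std::vector<double> pts;  // 3*i .. 3*i+2; vertices 0..3 are auxiliary
  std::vector<Tet> tets;
  std::vector<int> free_slots;
  std::vector<int> vert_tet;  // some alive tet incident to each vertex
  int n_aux = 4;
  int last_tet = 0;
  uint32_t rng_state = 0x9e3779b9u;

  const double* P(int i) const { return &pts[3 * i]; }
  int n_vertices() const { return static_cast<int>(pts.size() / 3); }
  int n_real() const { return n_vertices() - n_aux; }

  // init with one huge auxiliary tetrahedron strictly containing the box
  void init(double lo[3], double hi[3]) {
    double cx = 0.5 * (lo[0] + hi[0]), cy = 0.5 * (lo[1] + hi[1]),
           cz = 0.5 * (lo[2] + hi[2]);
    double R = 0.0;
    for (int k = 0; k < 3; ++k) R += (hi[k] - lo[k]) * (hi[k] - lo[k]);
    R = 30.0 * std::sqrt(std::max(R, 1.0));
    // regular tetrahedron with circumradius ~3R about the centre
    const double verts[4][3] = {{1, 1, 1}, {1, -1, -1}, {-1, 1, -1}, {-1, -1, 1}};
    pts.clear();
    for (int i = 0; i < 4; ++i) {
      pts.push_back(cx + 3.0 * R * verts[i][0]);
      pts.push_back(cy + 3.0 * R * verts[i][1]);
      pts.push_back(cz + 3.0 * R * verts[i][2]);
    }
    tets.clear();
    free_slots.clear();
    Tet t0;
    t0.v[0] = 0; t0.v[1] = 1; t0.v[2] = 2; t0.v[3] = 3;
    if (orient3d(P(0), P(1), P(2), P(3)) < 0) std::swap(t0.v[0], t0.v[1]);
    t0.nb[0] = t0.nb[1] = t0.nb[2] = t0.nb[3] = -1;
    t0.alive = true;
    tets.push_back(t0);
    vert_tet.assign(4, 0);
    last_tet = 0;
  }

  uint32_t rnd() {
    rng_state ^= rng_state << 13;
    rng_state ^= rng_state >> 17;
    rng_state ^= rng_state << 5;
    return rng_state;
  }

  int alloc_tet() {
    if (!free_slots.empty()) {
      int id = free_slots.back();
      free_slots.pop_back();
      return id;
    }
    tets.push_back(Tet());
    return static_cast<int>(tets.size()) - 1;
  }

  // visibility walk; returns an alive tet containing p (or touching it)
  int locate(const double* p, int hint) const {
    int t = (hint >= 0 && hint < (int)tets.size() && tets[hint].alive)
                ? hint : first_alive();
    int guard = 16 * (int)tets.size() + 64;
    uint32_t s = 0x12345u;
    while (guard-- > 0) {
      const Tet& T = tets[t];
      bool moved = false;
      s = s * 1664525u + 1013904223u;
      int off = s % 4;
      for (int k = 0; k < 4; ++k) {
        int i = (k + off) & 3;
        const double* A = P(T.v[(i + 1) & 3]);
        const double* B = P(T.v[(i + 2) & 3]);
        const double* C = P(T.v[(i + 3) & 3]);
        long double sp = orient3d(A, B, C, p);
        long double sv = orient3d(A, B, C, P(T.v[i]));
        if (sv != 0 && ((sp > 0) != (sv > 0)) && sp != 0) {
          if (T.nb[i] >= 0) {
            t = T.nb[i];
            moved = true;
            break;
          }
        }
      }
      if (!moved) return t;
    }
    return exhaustive_locate(p);
  }

  int first_alive() const {
    for (int i = (int)tets.size() - 1; i >= 0; --i)
      if (tets[i].alive) return i;
    throw std::runtime_error("triangulation has no alive tetrahedra");
  }

  int exhaustive_locate(const double* p) const {
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      const Tet& T = tets[t];
      bool in = true;
      for (int i = 0; i < 4 && in; ++i) {
        const double* A = P(T.v[(i + 1) & 3]);
        const double* B = P(T.v[(i + 2) & 3]);
        const double* C = P(T.v[(i + 3) & 3]);
        long double sp = orient3d(A, B, C, p);
        long double sv = orient3d(A, B, C, P(T.v[i]));
        if (sv != 0 && (sp > 0) != (sv > 0) && sp != 0) in = false;
      }
      if (in) return t;
    }
    throw std::runtime_error("point location failed");
  }

  bool conflicts(int t, const double* p) const {
    const Tet& T = tets[t];
    long double o = orient3d(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3]));
    long double s = insphere(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3]), p);
    if (o < 0) s = -s;
    return s > 0;
  }

  // insert one point (already appended to pts); id is its vertex index
  void insert_vertex(int id) {
    const double* p = P(id);
    int t0 = locate(p, last_tet);

    // grow cavity by BFS over conflicting tets
    std::vector<int> cavity;
    std::vector<int> stack;
    std::unordered_map<int, char> mark;  // 1 = in cavity, 2 = tested not
    stack.push_back(t0);
    mark[t0] = 1;
    cavity.push_back(t0);
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      for (int i = 0; i < 4; ++i) {
        int nbh = tets[t].nb[i];
        if (nbh < 0) continue;
        auto it = mark.find(nbh);
        if (it != mark.end()) continue;
        if (conflicts(nbh, p)) {
          mark[nbh] = 1;
          cavity.push_back(nbh);
          stack.push_back(nbh);
        } else {
          mark[nbh] = 2;
        }
      }
    }

    // star-shape repair: drop cavity tets with a boundary face not strictly
    // visible from p (rare, numerical)
    bool changed = true;
    while (changed && cavity.size() > 1) {
      changed = false;
      for (size_t ci = 0; ci < cavity.size(); ++ci) {
        int t = cavity[ci];
        const Tet& T = tets[t];
        bool bad = false;
        for (int i = 0; i < 4 && !bad; ++i) {
          int nbh = T.nb[i];
          bool boundary = (nbh < 0) || (mark[nbh] != 1);
          if (!boundary) continue;
          const double* A = P(T.v[(i + 1) & 3]);
          const double* B = P(T.v[(i + 2) & 3]);
          const double* C = P(T.v[(i + 3) & 3]);
          long double sp = orient3d(A, B, C, p);
          long double sv = orient3d(A, B, C, P(T.v[i]));
          // p must be strictly on the same side as the opposite vertex
          if (!(sv != 0 && ((sp > 0) == (sv > 0)) && sp != 0)) bad = true;
        }
        if (bad && t != t0) {
          mark[t] = 2;
          cavity.erase(cavity.begin() + ci);
          changed = true;
          break;
        }
      }
    }

    // collect boundary faces: (a,b,c) + outer tet + outer face index
    struct BFace { int a, b, c, outer, outer_face; };
    std::vector<BFace> bfaces;
    for (int t : cavity) {
      const Tet& T = tets[t];
      for (int i = 0; i < 4; ++i) {
        int nbh = T.nb[i];
        bool boundary = (nbh < 0) || (mark[nbh] != 1);
        if (!boundary) continue;
        BFace f;
        f.a = T.v[(i + 1) & 3];
        f.b = T.v[(i + 2) & 3];
        f.c = T.v[(i + 3) & 3];
        f.outer = nbh;
        f.outer_face = -1;
        if (nbh >= 0) {
          for (int j = 0; j < 4; ++j)
            if (tets[nbh].nb[j] == t) { f.outer_face = j; break; }
        }
        bfaces.push_back(f);
      }
    }

    // delete cavity
    for (int t : cavity) {
      tets[t].alive = false;
      free_slots.push_back(t);
    }

    // create new tets; match internal faces through edge->tet map
    std::unordered_map<uint64_t, std::pair<int, int>> edge_map;
    int newest = -1;
    for (const BFace& f : bfaces) {
      int id_t = alloc_tet();
      Tet& T = tets[id_t];
      T.v[0] = f.a; T.v[1] = f.b; T.v[2] = f.c; T.v[3] = id;
      if (orient3d(P(T.v[0]), P(T.v[1]), P(T.v[2]), P(T.v[3])) < 0)
        std::swap(T.v[0], T.v[1]);
      T.nb[0] = T.nb[1] = T.nb[2] = T.nb[3] = -1;
      T.alive = true;
      // face opposite the new vertex is the boundary face
      int p_pos = 3;
      for (int i = 0; i < 4; ++i) if (T.v[i] == id) p_pos = i;
      T.nb[p_pos] = f.outer;
      if (f.outer >= 0 && f.outer_face >= 0) tets[f.outer].nb[f.outer_face] = id_t;
      // remaining three faces each contain the new vertex and one edge of f
      for (int i = 0; i < 4; ++i) {
        if (i == p_pos) continue;
        // edge = the two face vertices other than v[i] and id
        int e[2]; int m = 0;
        for (int j = 0; j < 4; ++j) {
          if (j == i) continue;
          if (T.v[j] == id) continue;
          e[m++] = T.v[j];
        }
        if (m != 2) continue;
        if (e[0] > e[1]) std::swap(e[0], e[1]);
        uint64_t key = (uint64_t)e[0] << 32 | (uint32_t)e[1];
        auto it = edge_map.find(key);
        if (it == edge_map.end()) {
          edge_map[key] = {id_t, i};
        } else {
          int ot = it->second.first, of = it->second.second;
          T.nb[i] = ot;
          tets[ot].nb[of] = id_t;
          edge_map.erase(it);
        }
      }
      for (int i = 0; i < 4; ++i) {
        if ((int)vert_tet.size() <= T.v[i]) vert_tet.resize(T.v[i] + 1, -1);
        vert_tet[T.v[i]] = id_t;
      }
      newest = id_t;
    }
    if (newest >= 0) last_tet = newest;
  }

  // append and insert a batch of points; returns first new vertex id
  int insert_points(const std::vector<double>& xyz) {
    int first = n_vertices();
    size_t n = xyz.size() / 3;
    pts.insert(pts.end(), xyz.begin(), xyz.end());
    vert_tet.resize(n_vertices(), -1);
    for (size_t i = 0; i < n; ++i) insert_vertex(first + (int)i);
    return first;
  }

  // all real-vertex neighbours of vertex v (vertex ids, may include aux? no:
  // aux filtered by caller check); collects vertices sharing an alive tet.
  void vertex_neighbours(int v, std::vector<int>& out) const {
    out.clear();
    int t0 = vert_tet[v];
    if (t0 < 0 || !tets[t0].alive) t0 = find_incident_fallback(v);
    if (t0 < 0) return;
    std::vector<int> stack{t0};
    std::unordered_map<int, char> seen;
    seen[t0] = 1;
    std::unordered_map<int, char> vs;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      const Tet& T = tets[t];
      int pos = -1;
      for (int i = 0; i < 4; ++i) if (T.v[i] == v) pos = i;
      if (pos < 0) continue;
      for (int i = 0; i < 4; ++i) {
        if (i != pos) {
          int u = T.v[i];
          if (!vs.count(u)) { vs[u] = 1; out.push_back(u); }
          int nbh = T.nb[i];  // faces containing v are those not opposite v
          // neighbour opposite u still contains v
          if (nbh >= 0 && tets[nbh].alive && !seen.count(nbh)) {
            // only traverse neighbours sharing v
            const Tet& NT = tets[nbh];
            for (int j = 0; j < 4; ++j)
              if (NT.v[j] == v) { seen[nbh] = 1; stack.push_back(nbh); break; }
          }
        }
      }
    }
  }

  int find_incident_fallback(int v) const {
    for (int t = 0; t < (int)tets.size(); ++t)
      if (tets[t].alive)
        for (int i = 0; i < 4; ++i)
          if (tets[t].v[i] == v) return t;
    return -1;
  }

  // unique undirected edges among real vertices
  void real_edges(std::vector<std::pair<int, int>>& out) const {
    out.clear();
    std::unordered_map<uint64_t, char> seen;
    for (const Tet& T : tets) {
      if (!T.alive) continue;
      for (int i = 0; i < 4; ++i)
        for (int j = i + 1; j < 4; ++j) {
          int a = T.v[i], b = T.v[j];
          if (a < n_aux || b < n_aux) continue;
          if (a > b) std::swap(a, b);
          uint64_t key = (uint64_t)a << 32 | (uint32_t)b;
          if (seen.emplace(key, 1).second) out.emplace_back(a, b);
        }
    }
  }
};

}  // namespace fphant
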