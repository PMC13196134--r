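// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralization with walk-based
// point location, plus the union-find search for the critical alpha radius.
//
// Callers are expected to deduplicate and symbolically jitter the input
// (done on the R side) so that cospherical degeneracies, ubiquitous in
// regular pose grids, are broken before insertion.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

struct P3 {
  double x, y, z;
};

static inline double orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  double bx = b.x - a.x, by = b.y - a.y, bz = b.z - a.z;
  double cx = c.x - a.x, cy = c.y - a.y, cz = c.z - a.z;
  double dx = d.x - a.x, dy = d.y - a.y, dz = d.z - a.z;
  return bx * (cy * dz - cz * dy) - by * (cx * dz - cz * dx) + bz * (cx * dy - cy * dx);
}

struct Tet {
  int v[4];
  int nb[4];  // neighbor opposite v[i], -1 if none
  double cc[3], r2;
  bool alive;
  int epoch;  // visited marker for cavity search
};

// circumcenter of four points; returns false if nearly flat
static bool circumsphere(const P3& a, const P3& b, const P3& c, const P3& d,
                         double* cc, double& r2) {
  double m[3][3] = {{b.x - a.x, b.y - a.y, b.z - a.z},
                    {c.x - a.x, c.y - a.y, c.z - a.z},
                    {d.x - a.x, d.y - a.y, d.z - a.z}};
  double rhs[3] = {
      0.5 * (m[0][0] * m[0][0] + m[0][1] * m[0][1] + m[0][2] * m[0][2]),
      0.5 * (m[1][0] * m[1][0] + m[1][1] * m[1][1] + m[1][2] * m[1][2]),
      0.5 * (m[2][0] * m[2][0] + m[2][1] * m[2][1] + m[2][2] * m[2][2])};
  double det = m[0][0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
               m[0][1] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
               m[0][2] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]);
  if (std::fabs(det) < 1e-300) return false;
  double inv = 1.0 / det;
  double ux = inv * (rhs[0] * (m[1][1] * m[2][2] - m[1][2] * m[2][1]) -
                     m[0][1] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) +
                     m[0][2] * (rhs[1] * m[2][1] - m[1][1] * rhs[2]));
  double uy = inv * (m[0][0] * (rhs[1] * m[2][2] - m[1][2] * rhs[2]) -
                     rhs[0] * (m[1][0] * m[2][2] - m[1][2] * m[2][0]) +
                     m[0][2] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]));
  double uz = inv * (m[0][0] * (m[1][1] * rhs[2] - rhs[1] * m[2][1]) -
                     m[0][1] * (m[1][0] * rhs[2] - rhs[1] * m[2][0]) +
                     rhs[0] * (m[1][0] * m[2][1] - m[1][1] * m[2][0]));
  cc[0] = a.x + ux;
  cc[1] = a.y + uy;
  cc[2] = a.z + uz;
  r2 = ux * ux + uy * uy + uz * uz;
  return true;
}

struct Delaunay {
  std::vector<P3> pts;
  std::vector<Tet> tets;
  int n;  // number of real points (super vertices are n..n+3)
  int epoch_ctr = 0;

  bool in_sphere(const Tet& t, const P3& p) const {
    double dx = p.x - t.cc[0], dy = p.y - t.cc[1], dz = p.z - t.cc[2];
    return dx * dx + dy * dy + dz * dz < t.r2;
  }

  int make_tet(int a, int b, int c, int d) {
    if (orient3d(pts[a], pts[b], pts[c], pts[d]) < 0) std::swap(c, d);
    Tet t;
    t.v[0] = a; t.v[1] = b; t.v[2] = c; t.v[3] = d;
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    t.alive = true;
    t.epoch = -1;
    if (!circumsphere(pts[a], pts[b], pts[c], pts[d], t.cc, t.r2)) {
      // nearly flat tet (should not arise with jittered input): huge sphere
      t.cc[0] = t.cc[1] = t.cc[2] = 0.0;
      t.r2 = 1e300;
    }
    tets.push_back(t);
    return (int)tets.size() - 1;
  }

  // walk from tet `start` to a tet containing p
  int locate(int start, const P3& p) {
    int cur = start;
    int steps = 0, maxsteps = (int)tets.size() * 4 + 64;
    unsigned rng = 12345u;
    while (steps++ < maxsteps) {
      const Tet& t = tets[cur];
      int moved = -1;
      rng = rng * 1664525u + 1013904223u;
      int off = rng & 3;
      for (int k = 0; k < 4; ++k) {
        int i = (k + off) & 3;
        const P3& f0 = pts[t.v[(i + 1) & 3]];
        const P3& f1 = pts[t.v[(i + 2) & 3]];
        const P3& f2 = pts[t.v[(i + 3) & 3]];
        double si = orient3d(f0, f1, f2, pts[t.v[i]]);
        double sp = orient3d(f0, f1, f2, p);
        if (si * sp < 0) {
          if (t.nb[i] >= 0) {
            moved = t.nb[i];
            break;
          }
        }
      }
      if (moved < 0) return cur;
      cur = moved;
    }
    // walk failed (degenerate); fall back to linear scan by circumsphere
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && in_sphere(tets[i], p)) return i;
    return cur;
  }

  void insert(int ip, int& lastTet) {
    const P3& p = pts[ip];
    int t0 = locate(lastTet, p);
    if (!in_sphere(tets[t0], p)) {
      // roundoff: search neighborhood, then all
      int found = -1;
      for (int i = 0; i < 4 && found < 0; ++i) {
        int nb = tets[t0].nb[i];
        if (nb >= 0 && tets[nb].alive && in_sphere(tets[nb], p)) found = nb;
      }
      if (found < 0)
        for (int i = 0; i < (int)tets.size() && found < 0; ++i)
          if (tets[i].alive && in_sphere(tets[i], p)) found = i;
      if (found < 0) return;  // duplicate / unplaceable point: skip
      t0 = found;
    }
    // cavity = connected set of tets whose circumsphere contains p
    ++epoch_ctr;
    std::vector<int> bad, stack;
    stack.push_back(t0);
    tets[t0].epoch = epoch_ctr;
    while (!stack.empty()) {
      int t = stack.back();
      stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 4; ++i) {
        int nb = tets[t].nb[i];
        if (nb >= 0 && tets[nb].alive && tets[nb].epoch != epoch_ctr &&
            in_sphere(tets[nb], p)) {
          tets[nb].epoch = epoch_ctr;
          stack.push_back(nb);
        }
      }
    }
    // boundary faces and retriangulation
    struct BFace {
      int a, b, c;   // face vertices
      int outside;   // neighbor tet beyond the face (-1 if hull)
    };
    std::vector<BFace> faces;
    for (int t : bad) {
      for (int i = 0; i < 4; ++i) {
        int nb = tets[t].nb[i];
        bool nb_bad = nb >= 0 && tets[nb].alive && tets[nb].epoch == epoch_ctr;
        if (!nb_bad) {
          BFace f;
          f.a = tets[t].v[(i + 1) & 3];
          f.b = tets[t].v[(i + 2) & 3];
          f.c = tets[t].v[(i + 3) & 3];
          f.outside = nb;
          faces.push_back(f);
        }
      }
    }
    for (int t : bad) tets[t].alive = false;
    // map from undirected edge (containing p) to (tet, facet index)
    std::unordered_map<long long, std::pair<int, int>> open;
    open.reserve(faces.size() * 3);
    for (const BFace& f : faces) {
      int nt = make_tet(ip, f.a, f.b, f.c);
      // link across the boundary face: the facet of nt opposite vertex ip
      int fi = -1;
      for (int i = 0; i < 4; ++i)
        if (tets[nt].v[i] == ip) fi = i;
      tets[nt].nb[fi] = f.outside;
      if (f.outside >= 0) {
        Tet& o = tets[f.outside];
        for (int i = 0; i < 4; ++i) {
          int a = o.v[(i + 1) & 3], b = o.v[(i + 2) & 3], c = o.v[(i + 3) & 3];
          int s[3] = {a, b, c};
          std::sort(s, s + 3);
          int fs[3] = {f.a, f.b, f.c};
          std::sort(fs, fs + 3);
          if (s[0] == fs[0] && s[1] == fs[1] && s[2] == fs[2]) {
            o.nb[i] = nt;
            break;
          }
        }
      }
      // internal faces of the cavity fan: (ip, x, y) shared by two new tets
      int vv[3] = {f.a, f.b, f.c};
      for (int e = 0; e < 3; ++e) {
        int x = vv[e], y = vv[(e + 1) % 3];
        long long key = x < y ? ((long long)x << 32) | (unsigned)y
                              : ((long long)y << 32) | (unsigned)x;
        // facet of nt opposite the vertex not in {ip, x, y}
        int other = vv[(e + 2) % 3];
        int oi = -1;
        for (int i = 0; i < 4; ++i)
          if (tets[nt].v[i] == other) oi = i;
        auto it = open.find(key);
        if (it == open.end()) {
          open[key] = std::make_pair(nt, oi);
        } else {
          tets[nt].nb[oi] = it->second.first;
          tets[it->second.first].nb[it->second.second] = nt;
          open.erase(it);
        }
      }
      lastTet = nt;
    }
  }
};

// [[Rcpp::export]]
List cpp_delaunay3(NumericMatrix P) {
  int n = P.nrow();
  if (n < 4) stop("need at least 4 points");
  Delaunay D;
  D.n = n;
  D.pts.resize(n + 4);
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < n; ++i) {
    D.pts[i] = P3{P(i, 0), P(i, 1), P(i, 2)};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], P(i, d));
      hi[d] = std::max(hi[d], P(i, d));
    }
  }
  double cx = 0.5 * (lo[0] + hi[0]), cy = 0.5 * (lo[1] + hi[1]),
         cz = 0.5 * (lo[2] + hi[2]);
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  double s = 40.0 * (diag > 0 ? diag : 1.0);
  D.pts[n + 0] = P3{cx, cy, cz + 3 * s};
  D.pts[n + 1] = P3{cx - 3 * s, cy - 2 * s, cz - s};
  D.pts[n + 2] = P3{cx + 3 * s, cy - 2 * s, cz - s};
  D.pts[n + 3] = P3{cx, cy + 3 * s, cz - s};
  D.tets.reserve(8 * n);
  int last = D.make_tet(n, n + 1, n + 2, n + 3);
  for (int i = 0; i < n; ++i) {
    D.insert(i, last);
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    if (!D.tets[last].alive) {
      for (int t = (int)D.tets.size() - 1; t >= 0; --t)
        if (D.tets[t].alive) {
          last = t;
          break;
        }
    }
  }
  // collect tets without super vertices
  std::vector<int> keep;
  for (int t = 0; t < (int)D.tets.size(); ++t) {
    if (!D.tets[t].alive) continue;
    bool super = false;
    for (int k = 0; k < 4; ++k)
      if (D.tets[t].v[k] >= n) super = true;
    if (!super) keep.push_back(t);
  }
  int m = (int)keep.size();
  IntegerMatrix TT(m, 4);
  NumericVector rad(m), vol(m);
  for (int j = 0; j < m; ++j) {
    const Tet& t = D.tets[keep[j]];
    for (int k = 0; k < 4; ++k) TT(j, k) = t.v[k] + 1;
    rad[j] = std::sqrt(t.r2);
    vol[j] = std::fabs(orient3d(D.pts[t.v[0]], D.pts[t.v[1]], D.pts[t.v[2]],
                                D.pts[t.v[3]])) / 6.0;
  }
  return List::create(Named("tets") = TT, Named("circumradius") = rad,
                      Named("volume") = vol);
}

// ---- critical alpha: smallest radius for which the alpha complex is a ----
// ---- single face-connected component containing every input point    ----

struct DSU {
  std::vector<int> p;
  void init(int n) {
    p.resize(n);
    for (int i = 0; i < n; ++i) p[i] = i;
  }
  int find(int x) {
    while (p[x] != x) {
      p[x] = p[p[x]];
      x = p[x];
    }
    return x;
  }
  void unite(int a, int b) { p[find(a)] = find(b); }
};

// [[Rcpp::export]]
double cpp_critical_alpha(IntegerMatrix tets, NumericVector radii, int npoints) {
  int m = tets.nrow();
  if (m == 0) return NA_REAL;
  // face adjacency between tets
  std::unordered_map<long long, int> face_first;
  std::vector<std::pair<int, int>> adj;
  face_first.reserve(4 * m);
  for (int t = 0; t < m; ++t) {
    int v[4] = {tets(t, 0), tets(t, 1), tets(t, 2), tets(t, 3)};
    for (int i = 0; i < 4; ++i) {
      int f[3];
      int k = 0;
      for (int j = 0; j < 4; ++j)
        if (j != i) f[k++] = v[j];
      std::sort(f, f + 3);
      // pack 3 x 21-bit vertex ids
      long long key = ((long long)f[0] << 42) | ((long long)f[1] << 21) | f[2];
      auto it = face_first.find(key);
      if (it == face_first.end())
        face_first[key] = t;
      else
        adj.push_back(std::make_pair(it->second, t));
    }
  }
  std::vector<double> cand(radii.begin(), radii.end());
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  auto ok = [&](double alpha) -> bool {
    DSU dsu;
    dsu.init(m);
    std::vector<char> kept(m);
    int nkept = 0, root = -1;
    for (int t = 0; t < m; ++t)
      if (radii[t] <= alpha) {
        kept[t] = 1;
        ++nkept;
        root = t;
      }
    if (nkept == 0) return false;
    for (auto& e : adj)
      if (kept[e.first] && kept[e.second]) dsu.unite(e.first, e.second);
    int r0 = dsu.find(root);
    std::vector<char> covered(npoints + 1, 0);
    for (int t = 0; t < m; ++t) {
      if (!kept[t]) continue;
      if (dsu.find(t) != r0) return false;  // more than one component
      for (int k = 0; k < 4; ++k) covered[tets(t, k)] = 1;
    }
    for (int i = 1; i <= npoints; ++i)
      if (!covered[i]) return false;
    return true;
  };

  int lo = 0, hi = (int)cand.size() - 1;
  if (!ok(cand[hi])) return NA_REAL;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (ok(cand[mid]))
      hi = mid;
    else
      lo = mid + 1;
  }
  return cand[lo];
}
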