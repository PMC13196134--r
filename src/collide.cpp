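// Triangle-mesh interpenetration tests and the pose-grid collision sweep.
//
// Broad phase: axis-aligned BVH (median split on triangle centroids).
// Narrow phase: separating-axis test between triangle pairs.  Axis set is
// the two face normals, the nine edge-edge cross products, and the six
// in-plane edge normals (needed for coplanar pairs).  Surface contact counts
// as interpenetration: a pair is declared disjoint only when the projection
// gap exceeds CONTACT_TOL on some axis.
//
// Containment (one watertight mesh fully inside the other, no surface
// crossing) is decided by ray-crossing parity along a fixed generic
// direction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

static const double CONTACT_TOL = 1e-9;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 vsub(const Vec3& a, const Vec3& b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double vdot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 vcross(const Vec3& a, const Vec3& b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double vnorm2(const Vec3& a) { return vdot(a, a); }

struct Tri {
  Vec3 v[3];
};

// project triangle on axis
static inline void project(const Tri& t, const Vec3& ax, double& lo, double& hi) {
  double d0 = vdot(t.v[0], ax), d1 = vdot(t.v[1], ax), d2 = vdot(t.v[2], ax);
  lo = std::min(d0, std::min(d1, d2));
  hi = std::max(d0, std::max(d1, d2));
}

// true iff axis separates the two triangles (gap beyond tolerance)
static inline bool separates(const Tri& a, const Tri& b, const Vec3& ax) {
  double n2 = vnorm2(ax);
  if (n2 < 1e-24) return false;  // degenerate axis carries no information
  double s = CONTACT_TOL * std::sqrt(n2);
  double alo, ahi, blo, bhi;
  project(a, ax, alo, ahi);
  project(b, ax, blo, bhi);
  return (ahi < blo - s) || (bhi < alo - s);
}

static bool tri_tri_overlap(const Tri& a, const Tri& b) {
  Vec3 ea[3] = {vsub(a.v[1], a.v[0]), vsub(a.v[2], a.v[1]), vsub(a.v[0], a.v[2])};
  Vec3 eb[3] = {vsub(b.v[1], b.v[0]), vsub(b.v[2], b.v[1]), vsub(b.v[0], b.v[2])};
  Vec3 na = vcross(ea[0], ea[1]);
  Vec3 nb = vcross(eb[0], eb[1]);
  if (separates(a, b, na)) return false;
  if (separates(a, b, nb)) return false;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (separates(a, b, vcross(ea[i], eb[j]))) return false;
  // in-plane edge normals: complete the axis set for (near-)coplanar pairs
  for (int i = 0; i < 3; ++i) {
    if (separates(a, b, vcross(na, ea[i]))) return false;
    if (separates(a, b, vcross(nb, eb[i]))) return false;
  }
  return true;
}

// ---------------------------------------------------------------- BVH ----

struct BVHNode {
  double bmin[3], bmax[3];
  int left, right;   // children, or -1 for leaf
  int start, count;  // triangle index range (leaves)
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<int> order;
  std::vector<BVHNode> nodes;

  void tri_bounds(int t, double* bmin, double* bmax) const {
    const Tri& tr = tris[t];
    for (int k = 0; k < 3; ++k) {
      const double c[3] = {tr.v[k].x, tr.v[k].y, tr.v[k].z};
      for (int d = 0; d < 3; ++d) {
        bmin[d] = std::min(bmin[d], c[d]);
        bmax[d] = std::max(bmax[d], c[d]);
      }
    }
  }

  int build(int start, int count) {
    BVHNode nd;
    for (int d = 0; d < 3; ++d) {
      nd.bmin[d] = 1e300;
      nd.bmax[d] = -1e300;
    }
    for (int i = start; i < start + count; ++i) tri_bounds(order[i], nd.bmin, nd.bmax);
    nd.left = nd.right = -1;
    nd.start = start;
    nd.count = count;
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (count <= 4) return id;
    // split on the longest axis of the centroid bounds
    double cmin[3] = {1e300, 1e300, 1e300}, cmax[3] = {-1e300, -1e300, -1e300};
    for (int i = start; i < start + count; ++i) {
      const Tri& tr = tris[order[i]];
      double c[3] = {(tr.v[0].x + tr.v[1].x + tr.v[2].x) / 3.0,
                     (tr.v[0].y + tr.v[1].y + tr.v[2].y) / 3.0,
                     (tr.v[0].z + tr.v[1].z + tr.v[2].z) / 3.0};
      for (int d = 0; d < 3; ++d) {
        cmin[d] = std::min(cmin[d], c[d]);
        cmax[d] = std::max(cmax[d], c[d]);
      }
    }
    int axis = 0;
    double ext = cmax[0] - cmin[0];
    for (int d = 1; d < 3; ++d)
      if (cmax[d] - cmin[d] > ext) {
        ext = cmax[d] - cmin[d];
        axis = d;
      }
    if (ext <= 0) return id;  // all centroids coincide; keep as leaf
    int mid = start + count / 2;
    std::nth_element(order.begin() + start, order.begin() + mid,
                     order.begin() + start + count, [&](int ia, int ib) {
                       const Tri &ta = tris[ia], &tb = tris[ib];
                       double ca = axis == 0 ? ta.v[0].x + ta.v[1].x + ta.v[2].x
                                 : axis == 1 ? ta.v[0].y + ta.v[1].y + ta.v[2].y
                                             : ta.v[0].z + ta.v[1].z + ta.v[2].z;
                       double cb = axis == 0 ? tb.v[0].x + tb.v[1].x + tb.v[2].x
                                 : axis == 1 ? tb.v[0].y + tb.v[1].y + tb.v[2].y
                                             : tb.v[0].z + tb.v[1].z + tb.v[2].z;
                       return ca < cb;
                     });
    int l = build(start, mid - start);
    int r = build(mid, start + count - mid);
    nodes[id].left = l;
    nodes[id].right = r;
    nodes[id].count = 0;
    return id;
  }

  void init(const NumericMatrix& V, const IntegerMatrix& F) {
    int m = F.nrow();
    tris.resize(m);
    order.resize(m);
    for (int i = 0; i < m; ++i) {
      for (int k = 0; k < 3; ++k) {
        int vi = F(i, k) - 1;
        tris[i].v[k] = Vec3{V(vi, 0), V(vi, 1), V(vi, 2)};
      }
      order[i] = i;
    }
    nodes.clear();
    nodes.reserve(2 * m);
    build(0, m);
  }

  // does query triangle (with bounds qmin/qmax) intersect any stored triangle?
  bool query(const Tri& q, const double* qmin, const double* qmax) const {
    static thread_local std::vector<int> stack;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const BVHNode& nd = nodes[id];
      bool out = false;
      for (int d = 0; d < 3; ++d)
        if (qmin[d] > nd.bmax[d] + CONTACT_TOL || qmax[d] < nd.bmin[d] - CONTACT_TOL) {
          out = true;
          break;
        }
      if (out) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i)
          if (tri_tri_overlap(tris[order[i]], q)) return true;
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    return false;
  }

  // ray-crossing parity for point containment (generic fixed direction)
  bool contains(const Vec3& p) const {
    const Vec3 dir{0.2398171536, 0.9371063547, 0.2542088353};
    static thread_local std::vector<int> stack;
    stack.clear();
    stack.push_back(0);
    int crossings = 0;
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      const BVHNode& nd = nodes[id];
      // slab test for the ray against the node box
      double t0 = 0.0, t1 = 1e300;
      const double o[3] = {p.x, p.y, p.z};
      const double d[3] = {dir.x, dir.y, dir.z};
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        double inv = 1.0 / d[k];
        double ta = (nd.bmin[k] - o[k]) * inv;
        double tb = (nd.bmax[k] - o[k]) * inv;
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
        if (t0 > t1) {
          miss = true;
          break;
        }
      }
      if (miss) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          const Tri& tr = tris[order[i]];
          // Moeller-Trumbore
          Vec3 e1 = vsub(tr.v[1], tr.v[0]);
          Vec3 e2 = vsub(tr.v[2], tr.v[0]);
          Vec3 pv = vcross(dir, e2);
          double det = vdot(e1, pv);
          if (std::fabs(det) < 1e-14) continue;
          double invd = 1.0 / det;
          Vec3 tv = vsub(p, tr.v[0]);
          double u = vdot(tv, pv) * invd;
          if (u < 0.0 || u > 1.0) continue;
          Vec3 qv = vcross(tv, e1);
          double v = vdot(dir, qv) * invd;
          if (v < 0.0 || u + v > 1.0) continue;
          double t = vdot(e2, qv) * invd;
          if (t > 1e-12) ++crossings;
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    return (crossings % 2) == 1;
  }
};

static bool meshes_overlap(const BVH& ta, const BVH& tb) {
  // surface-surface contact: query every triangle of b against a's BVH
  for (size_t i = 0; i < tb.tris.size(); ++i) {
    const Tri& q = tb.tris[i];
    double qmin[3] = {1e300, 1e300, 1e300}, qmax[3] = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 3; ++k) {
      const double c[3] = {q.v[k].x, q.v[k].y, q.v[k].z};
      for (int d = 0; d < 3; ++d) {
        qmin[d] = std::min(qmin[d], c[d]);
        qmax[d] = std::max(qmax[d], c[d]);
      }
    }
    if (ta.query(q, qmin, qmax)) return true;
  }
  // no surface crossing: full containment either way still interpenetrates
  if (ta.contains(tb.tris[0].v[0])) return true;
  if (tb.contains(ta.tris[0].v[0])) return true;
  return false;
}

// narrow-phase entry point, used by the test suite's SAT cross-check
// [[Rcpp::export]]
bool cpp_tri_pair_overlap(NumericMatrix t1, NumericMatrix t2) {
  Tri a, b;
  for (int k = 0; k < 3; ++k) {
    a.v[k] = Vec3{t1(k, 0), t1(k, 1), t1(k, 2)};
    b.v[k] = Vec3{t2(k, 0), t2(k, 1), t2(k, 2)};
  }
  return tri_tri_overlap(a, b);
}

// [[Rcpp::export]]
bool cpp_meshes_intersect(NumericMatrix VA, IntegerMatrix FA, NumericMatrix VB,
                          IntegerMatrix FB) {
  BVH ta, tb;
  ta.init(VA, FA);
  tb.init(VB, FB);
  return meshes_overlap(ta, tb);
}

// [[Rcpp::export]]
bool cpp_point_in_mesh(NumericVector p, NumericMatrix V, IntegerMatrix F) {
  BVH t;
  t.init(V, F);
  return t.contains(Vec3{p[0], p[1], p[2]});
}

// Collision sweep over a pose grid.
// rot: nPoses x 9 world rotation matrices (row-major), applied about `cor`
// after the reference transform refR/refT has placed the distal mesh.
// Returns 1 (viable, no interpenetration) or 0 per pose.
// [[Rcpp::export]]
IntegerVector cpp_sweep_collide(NumericMatrix VA, IntegerMatrix FA,
                                NumericMatrix VB, IntegerMatrix FB,
                                NumericMatrix rot, NumericVector cor,
                                NumericMatrix refR, NumericVector refT,
                                bool verbose = false) {
  BVH prox;
  prox.init(VA, FA);
  const int nv = VB.nrow(), nf = FB.nrow(), np = rot.nrow();

  // distal vertices in reference placement, relative to the COR
  std::vector<Vec3> ref(nv);
  for (int i = 0; i < nv; ++i) {
    double x = VB(i, 0), y = VB(i, 1), z = VB(i, 2);
    ref[i] = Vec3{
        refR(0, 0) * x + refR(0, 1) * y + refR(0, 2) * z + refT[0] - cor[0],
        refR(1, 0) * x + refR(1, 1) * y + refR(1, 2) * z + refT[1] - cor[1],
        refR(2, 0) * x + refR(2, 1) * y + refR(2, 2) * z + refT[2] - cor[2]};
  }
  std::vector<int> f0(nf), f1(nf), f2(nf);
  for (int i = 0; i < nf; ++i) {
    f0[i] = FB(i, 0) - 1;
    f1[i] = FB(i, 1) - 1;
    f2[i] = FB(i, 2) - 1;
  }

  IntegerVector code(np);
  std::vector<Vec3> w(nv);
  const BVHNode& root = prox.nodes[0];
  int last_hit = -1;  // distal triangle that collided at the previous pose;
                      // neighboring grid poses usually collide there too
  for (int ip = 0; ip < np; ++ip) {
    if (ip % 2048 == 0) Rcpp::checkUserInterrupt();
    const double r00 = rot(ip, 0), r01 = rot(ip, 1), r02 = rot(ip, 2);
    const double r10 = rot(ip, 3), r11 = rot(ip, 4), r12 = rot(ip, 5);
    const double r20 = rot(ip, 6), r21 = rot(ip, 7), r22 = rot(ip, 8);
    double bmin[3] = {1e300, 1e300, 1e300}, bmax[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < nv; ++i) {
      const Vec3& v = ref[i];
      Vec3 p{r00 * v.x + r01 * v.y + r02 * v.z + cor[0],
             r10 * v.x + r11 * v.y + r12 * v.z + cor[1],
             r20 * v.x + r21 * v.y + r22 * v.z + cor[2]};
      w[i] = p;
      bmin[0] = std::min(bmin[0], p.x);
      bmax[0] = std::max(bmax[0], p.x);
      bmin[1] = std::min(bmin[1], p.y);
      bmax[1] = std::max(bmax[1], p.y);
      bmin[2] = std::min(bmin[2], p.z);
      bmax[2] = std::max(bmax[2], p.z);
    }
    bool boxes_disjoint = false;
    for (int d = 0; d < 3; ++d)
      if (bmin[d] > root.bmax[d] + CONTACT_TOL || bmax[d] < root.bmin[d] - CONTACT_TOL) {
        boxes_disjoint = true;
        break;
      }
    bool hit = false;
    if (!boxes_disjoint) {
      if (last_hit >= 0) {
        Tri q{{w[f0[last_hit]], w[f1[last_hit]], w[f2[last_hit]]}};
        double qmin[3] = {1e300, 1e300, 1e300},
               qmax[3] = {-1e300, -1e300, -1e300};
        for (int k = 0; k < 3; ++k) {
          const double c[3] = {q.v[k].x, q.v[k].y, q.v[k].z};
          for (int d = 0; d < 3; ++d) {
            qmin[d] = std::min(qmin[d], c[d]);
            qmax[d] = std::max(qmax[d], c[d]);
          }
        }
        if (prox.query(q, qmin, qmax)) hit = true;
      }
      for (int i = 0; i < nf && !hit; ++i) {
        if (i == last_hit) continue;
        Tri q{{w[f0[i]], w[f1[i]], w[f2[i]]}};
        double qmin[3] = {1e300, 1e300, 1e300}, qmax[3] = {-1e300, -1e300, -1e300};
        for (int k = 0; k < 3; ++k) {
          const double c[3] = {q.v[k].x, q.v[k].y, q.v[k].z};
          for (int d = 0; d < 3; ++d) {
            qmin[d] = std::min(qmin[d], c[d]);
            qmax[d] = std::max(qmax[d], c[d]);
          }
        }
        if (prox.query(q, qmin, qmax)) {
          hit = true;
          last_hit = i;
        }
      }
      if (!hit) {
        // containment without surface crossing
        if (prox.contains(w[0])) hit = true;
        else {
          // proximal inside distal is only possible when the distal box
          // encloses the proximal box; then brute-force ray parity suffices
          bool enclosed = true;
          for (int d = 0; d < 3; ++d)
            if (bmin[d] > root.bmin[d] || bmax[d] < root.bmax[d]) {
              enclosed = false;
              break;
            }
          if (enclosed) {
            const Vec3 dir{0.2398171536, 0.9371063547, 0.2542088353};
            const Vec3 p = prox.tris[0].v[0];
            int crossings = 0;
            for (int i = 0; i < nf; ++i) {
              Vec3 e1 = vsub(w[f1[i]], w[f0[i]]);
              Vec3 e2 = vsub(w[f2[i]], w[f0[i]]);
              Vec3 pv = vcross(dir, e2);
              double det = vdot(e1, pv);
              if (std::fabs(det) < 1e-14) continue;
              double invd = 1.0 / det;
              Vec3 tv = vsub(p, w[f0[i]]);
              double u = vdot(tv, pv) * invd;
              if (u < 0.0 || u > 1.0) continue;
              Vec3 qv = vcross(tv, e1);
              double v = vdot(dir, qv) * invd;
              if (v < 0.0 || u + v > 1.0) continue;
              double t = vdot(e2, qv) * invd;
              if (t > 1e-12) ++crossings;
            }
            if (crossings % 2 == 1) hit = true;
          }
        }
      }
    }
    code[ip] = hit ? 0 : 1;
    if (verbose && (ip + 1) % 10000 == 0)
      Rcout << "  swept " << (ip + 1) << "/" << np << " poses\n";
  }
  return code;
}
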