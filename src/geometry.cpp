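// Bounding-volume-hierarchy accelerated triangle-mesh queries.
//
// Exact closest point on a triangle set and bidirectional ray (line)
// intersection, used as the correspondence kernel for ICP and for the
// perpendicular distance map. Results are identical to brute force over all
// triangles; ties are broken by the lowest face index for determinism.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 vsub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 vadd(const Vec3 &a, const Vec3 &b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 vscale(const Vec3 &a, double s) { return {a.x * s, a.y * s, a.z * s}; }
inline double vdot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 vcross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, 5.1.5.
Vec3 closestPointTriangle(const Vec3 &p, const Vec3 &a, const Vec3 &b, const Vec3 &c) {
  Vec3 ab = vsub(b, a), ac = vsub(c, a), ap = vsub(p, a);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;

  Vec3 bp = vsub(p, b);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return vadd(a, vscale(ab, v));
  }

  Vec3 cp = vsub(p, c);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return vadd(a, vscale(ac, w));
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return vadd(b, vscale(vsub(c, b), w));
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return vadd(a, vadd(vscale(ab, v), vscale(ac, w)));
}

// Moller-Trumbore without the t >= 0 restriction: intersects the infinite
// line origin + t * dir with a triangle. Returns true with t set on hit.
bool lineTriangle(const Vec3 &orig, const Vec3 &dir,
                  const Vec3 &a, const Vec3 &b, const Vec3 &c, double &t) {
  const double eps = 1e-12;
  Vec3 e1 = vsub(b, a), e2 = vsub(c, a);
  Vec3 pv = vcross(dir, e2);
  double det = vdot(e1, pv);
  if (std::fabs(det) < eps) return false;  // parallel (grazing counts as miss)
  double invDet = 1.0 / det;
  Vec3 tv = vsub(orig, a);
  double u = vdot(tv, pv) * invDet;
  if (u < -1e-12 || u > 1.0 + 1e-12) return false;
  Vec3 qv = vcross(tv, e1);
  double v = vdot(dir, qv) * invDet;
  if (v < -1e-12 || u + v > 1.0 + 1e-12) return false;
  t = vdot(e2, qv) * invDet;
  return true;
}

struct Node {
  double lo[3], hi[3];
  int left = -1, right = -1;  // children, -1 for leaf
  int start = 0, count = 0;   // leaf: range into order[]
};

struct BVH {
  std::vector<Vec3> va, vb, vc;  // triangle corners, in face order
  std::vector<Node> nodes;
  std::vector<int> order;  // permutation of face indices

  Vec3 corner(int f, int which) const {
    switch (which) {
      case 0: return va[f];
      case 1: return vb[f];
      default: return vc[f];
    }
  }
};

void nodeBounds(BVH &bvh, Node &nd) {
  for (int k = 0; k < 3; ++k) {
    nd.lo[k] = std::numeric_limits<double>::infinity();
    nd.hi[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = nd.start; i < nd.start + nd.count; ++i) {
    int f = bvh.order[i];
    for (int w = 0; w < 3; ++w) {
      Vec3 p = bvh.corner(f, w);
      nd.lo[0] = std::min(nd.lo[0], p.x); nd.hi[0] = std::max(nd.hi[0], p.x);
      nd.lo[1] = std::min(nd.lo[1], p.y); nd.hi[1] = std::max(nd.hi[1], p.y);
      nd.lo[2] = std::min(nd.lo[2], p.z); nd.hi[2] = std::max(nd.hi[2], p.z);
    }
  }
}

int buildNode(BVH &bvh, std::vector<Vec3> &centroids, int start, int count) {
  const int LEAF = 8;
  Node nd;
  nd.start = start;
  nd.count = count;
  nodeBounds(bvh, nd);
  int idx = (int)bvh.nodes.size();
  bvh.nodes.push_back(nd);
  if (count <= LEAF) return idx;

  // split on the longest axis at the median centroid
  double ext[3] = {nd.hi[0] - nd.lo[0], nd.hi[1] - nd.lo[1], nd.hi[2] - nd.lo[2]};
  int axis = 0;
  if (ext[1] > ext[axis]) axis = 1;
  if (ext[2] > ext[axis]) axis = 2;

  int mid = start + count / 2;
  std::nth_element(bvh.order.begin() + start, bvh.order.begin() + mid,
                   bvh.order.begin() + start + count,
                   [&](int f1, int f2) {
                     const Vec3 &c1 = centroids[f1], &c2 = centroids[f2];
                     double a1 = axis == 0 ? c1.x : (axis == 1 ? c1.y : c1.z);
                     double a2 = axis == 0 ? c2.x : (axis == 1 ? c2.y : c2.z);
                     if (a1 != a2) return a1 < a2;
                     return f1 < f2;  // deterministic
                   });
  if (mid == start || mid == start + count) return idx;  // degenerate: keep leaf

  int l = buildNode(bvh, centroids, start, mid - start);
  int r = buildNode(bvh, centroids, mid, start + count - mid);
  bvh.nodes[idx].left = l;
  bvh.nodes[idx].right = r;
  bvh.nodes[idx].count = 0;
  return idx;
}

double boxDist2(const Node &nd, const Vec3 &p) {
  double d2 = 0.0;
  double c[3] = {p.x, p.y, p.z};
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (c[k] < nd.lo[k]) d = nd.lo[k] - c[k];
    else if (c[k] > nd.hi[k]) d = c[k] - nd.hi[k];
    d2 += d * d;
  }
  return d2;
}

// Minimum |t| at which the line touches the node's box; +Inf when it misses.
double boxLineMinAbsT(const Node &nd, const Vec3 &o, const Vec3 &d) {
  double t0 = -std::numeric_limits<double>::infinity();
  double t1 = std::numeric_limits<double>::infinity();
  double oo[3] = {o.x, o.y, o.z}, dd[3] = {d.x, d.y, d.z};
  for (int k = 0; k < 3; ++k) {
    if (std::fabs(dd[k]) < 1e-300) {
      if (oo[k] < nd.lo[k] || oo[k] > nd.hi[k]) return std::numeric_limits<double>::infinity();
    } else {
      double a = (nd.lo[k] - oo[k]) / dd[k];
      double b = (nd.hi[k] - oo[k]) / dd[k];
      if (a > b) std::swap(a, b);
      t0 = std::max(t0, a);
      t1 = std::min(t1, b);
      if (t0 > t1) return std::numeric_limits<double>::infinity();
    }
  }
  if (t0 <= 0.0 && t1 >= 0.0) return 0.0;
  return std::min(std::fabs(t0), std::fabs(t1));
}

BVH *asBVH(SEXP ptr) {
  XPtr<BVH> xp(ptr);
  return xp.get();
}

}  // namespace

// [[Rcpp::export(name = ".bvh_build")]]
SEXP bvh_build(NumericMatrix V, IntegerMatrix F) {
  if (V.ncol() != 3) stop("vertices must be an n x 3 matrix");
  if (F.ncol() != 3) stop("faces must be an m x 3 matrix");
  int m = F.nrow();
  if (m < 1) stop("mesh has no faces");
  BVH *bvh = new BVH();
  bvh->va.resize(m);
  bvh->vb.resize(m);
  bvh->vc.resize(m);
  std::vector<Vec3> centroids(m);
  int nv = V.nrow();
  for (int f = 0; f < m; ++f) {
    int i = F(f, 0) - 1, j = F(f, 1) - 1, k = F(f, 2) - 1;
    if (i < 0 || j < 0 || k < 0 || i >= nv || j >= nv || k >= nv) {
      delete bvh;
      stop("face index out of range");
    }
    bvh->va[f] = {V(i, 0), V(i, 1), V(i, 2)};
    bvh->vb[f] = {V(j, 0), V(j, 1), V(j, 2)};
    bvh->vc[f] = {V(k, 0), V(k, 1), V(k, 2)};
    centroids[f] = vscale(vadd(vadd(bvh->va[f], bvh->vb[f]), bvh->vc[f]), 1.0 / 3.0);
  }
  bvh->order.resize(m);
  for (int f = 0; f < m; ++f) bvh->order[f] = f;
  buildNode(*bvh, centroids, 0, m);
  XPtr<BVH> xp(bvh, true);
  return xp;
}

// [[Rcpp::export(name = ".bvh_closest")]]
List bvh_closest(SEXP ptr, NumericMatrix Q) {
  BVH *bvh = asBVH(ptr);
  int nq = Q.nrow();
  NumericMatrix pts(nq, 3);
  NumericVector d2out(nq);
  IntegerVector face(nq);

  std::vector<int> stack;
  stack.reserve(64);
  for (int q = 0; q < nq; ++q) {
    Vec3 p = {Q(q, 0), Q(q, 1), Q(q, 2)};
    double best = std::numeric_limits<double>::infinity();
    int bestFace = -1;
    Vec3 bestPt = {0, 0, 0};
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node &nd = bvh->nodes[ni];
      if (boxDist2(nd, p) > best) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = bvh->order[i];
          Vec3 cp = closestPointTriangle(p, bvh->va[f], bvh->vb[f], bvh->vc[f]);
          Vec3 dv = vsub(p, cp);
          double d2 = vdot(dv, dv);
          if (d2 < best || (d2 == best && f < bestFace)) {
            best = d2;
            bestFace = f;
            bestPt = cp;
          }
        }
      } else {
        // visit the nearer child first
        double dl = boxDist2(bvh->nodes[nd.left], p);
        double dr = boxDist2(bvh->nodes[nd.right], p);
        if (dl <= dr) {
          stack.push_back(nd.right);
          stack.push_back(nd.left);
        } else {
          stack.push_back(nd.left);
          stack.push_back(nd.right);
        }
      }
    }
    pts(q, 0) = bestPt.x;
    pts(q, 1) = bestPt.y;
    pts(q, 2) = bestPt.z;
    d2out[q] = best;
    face[q] = bestFace + 1;
  }
  return List::create(_["point"] = pts, _["dist2"] = d2out, _["face"] = face);
}

// [[Rcpp::export(name = ".bvh_line_hits")]]
List bvh_line_hits(SEXP ptr, NumericMatrix O, NumericMatrix D) {
  BVH *bvh = asBVH(ptr);
  int nq = O.nrow();
  if (D.nrow() != nq || D.ncol() != 3) stop("direction matrix must match origins");
  NumericVector tout(nq);
  IntegerVector face(nq);

  std::vector<int> stack;
  stack.reserve(64);
  for (int q = 0; q < nq; ++q) {
    Vec3 o = {O(q, 0), O(q, 1), O(q, 2)};
    Vec3 d = {D(q, 0), D(q, 1), D(q, 2)};
    double bestAbs = std::numeric_limits<double>::infinity();
    double bestT = NA_REAL;
    int bestFace = NA_INTEGER;
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const Node &nd = bvh->nodes[ni];
      if (boxLineMinAbsT(nd, o, d) >= bestAbs) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          int f = bvh->order[i];
          double t;
          if (lineTriangle(o, d, bvh->va[f], bvh->vb[f], bvh->vc[f], t)) {
            double at = std::fabs(t);
            if (at < bestAbs || (at == bestAbs && f < bestFace)) {
              bestAbs = at;
              bestT = t;
              bestFace = f + 1;
            }
          }
        }
      } else {
        stack.push_back(nd.right);
        stack.push_back(nd.left);
      }
    }
    tout[q] = bestT;
    face[q] = bestFace;
  }
  return List::create(_["t"] = tout, _["face"] = face);
}

// [[Rcpp::export(name = ".bvh_all_line_hits")]]
List bvh_all_line_hits(SEXP ptr, NumericVector orig, NumericVector dir) {
  // All line-triangle hits for a single line (used by undercut diagnostics).
  BVH *bvh = asBVH(ptr);
  Vec3 o = {orig[0], orig[1], orig[2]};
  Vec3 d = {dir[0], dir[1], dir[2]};
  std::vector<double> ts;
  std::vector<int> faces;
  std::vector<int> stack;
  stack.push_back(0);
  while (!stack.empty()) {
    int ni = stack.back();
    stack.pop_back();
    const Node &nd = bvh->nodes[ni];
    if (!std::isfinite(boxLineMinAbsT(nd, o, d))) continue;
    if (nd.left < 0) {
      for (int i = nd.start; i < nd.start + nd.count; ++i) {
        int f = bvh->order[i];
        double t;
        if (lineTriangle(o, d, bvh->va[f], bvh->vb[f], bvh->vc[f], t)) {
          ts.push_back(t);
          faces.push_back(f + 1);
        }
      }
    } else {
      stack.push_back(nd.right);
      stack.push_back(nd.left);
    }
  }
  return List::create(_["t"] = wrap(ts), _["face"] = wrap(faces));
}
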