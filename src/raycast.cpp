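#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

// First-hit radial ray casting against a triangle soup.
// Moller-Trumbore intersection behind a median-split AABB BVH.
// All rays share one origin (the fitted joint center), so the BVH is built
// once per mesh and traversed per ray. Results are required to be identical
// to an exhaustive loop over all triangles (see brute_cast.cpp, which is an
// independent implementation used as oracle).

namespace {

struct BVHNode {
  double bmin[3], bmax[3];
  int left;   // child index, -1 for leaf
  int right;
  int start;  // leaf: first index into tri order
  int count;  // leaf: number of triangles
};

struct BVH {
  std::vector<BVHNode> nodes;
  std::vector<int> order;          // triangle indices, leaf-contiguous
  std::vector<double> v0, e1, e2;  // 3*ntri, precomputed edges
};

const double kDetEps = 1e-12;

inline void tri_bounds(const Rcpp::NumericMatrix& V, const Rcpp::IntegerMatrix& F,
                       int t, double* lo, double* hi) {
  for (int k = 0; k < 3; ++k) { lo[k] = std::numeric_limits<double>::infinity(); hi[k] = -lo[k]; }
  for (int j = 0; j < 3; ++j) {
    int vi = F(t, j) - 1;
    for (int k = 0; k < 3; ++k) {
      double c = V(vi, k);
      if (c < lo[k]) lo[k] = c;
      if (c > hi[k]) hi[k] = c;
    }
  }
}

int build_node(BVH& bvh, std::vector<int>& idx, int start, int end,
               const std::vector<double>& cent,
               const Rcpp::NumericMatrix& V, const Rcpp::IntegerMatrix& F) {
  BVHNode node;
  for (int k = 0; k < 3; ++k) {
    node.bmin[k] = std::numeric_limits<double>::infinity();
    node.bmax[k] = -node.bmin[k];
  }
  double lo[3], hi[3];
  for (int i = start; i < end; ++i) {
    tri_bounds(V, F, idx[i], lo, hi);
    for (int k = 0; k < 3; ++k) {
      if (lo[k] < node.bmin[k]) node.bmin[k] = lo[k];
      if (hi[k] > node.bmax[k]) node.bmax[k] = hi[k];
    }
  }
  int n = end - start;
  int self = (int)bvh.nodes.size();
  bvh.nodes.push_back(node);
  if (n <= 8) {
    bvh.nodes[self].left = bvh.nodes[self].right = -1;
    bvh.nodes[self].start = start;
    bvh.nodes[self].count = n;
    return self;
  }
  // split on the longest centroid axis at the median
  double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
  for (int i = start; i < end; ++i)
    for (int k = 0; k < 3; ++k) {
      double c = cent[3 * idx[i] + k];
      if (c < clo[k]) clo[k] = c;
      if (c > chi[k]) chi[k] = c;
    }
  int axis = 0;
  double ext = chi[0] - clo[0];
  for (int k = 1; k < 3; ++k)
    if (chi[k] - clo[k] > ext) { ext = chi[k] - clo[k]; axis = k; }
  int mid = start + n / 2;
  std::nth_element(idx.begin() + start, idx.begin() + mid, idx.begin() + end,
                   [&](int a, int b) { return cent[3 * a + axis] < cent[3 * b + axis]; });
  if (ext <= 0.0) mid = start + n / 2;  // degenerate spread: plain median split
  int l = build_node(bvh, idx, start, mid, cent, V, F);
  int r = build_node(bvh, idx, mid, end, cent, V, F);
  bvh.nodes[self].left = l;
  bvh.nodes[self].right = r;
  bvh.nodes[self].start = -1;
  bvh.nodes[self].count = 0;
  return self;
}

BVH build_bvh(const Rcpp::NumericMatrix& V, const Rcpp::IntegerMatrix& F) {
  BVH bvh;
  int nf = F.nrow();
  bvh.v0.resize(3 * nf); bvh.e1.resize(3 * nf); bvh.e2.resize(3 * nf);
  std::vector<double> cent(3 * nf);
  std::vector<int> idx(nf);
  for (int t = 0; t < nf; ++t) {
    idx[t] = t;
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      bvh.v0[3 * t + k] = V(a, k);
      bvh.e1[3 * t + k] = V(b, k) - V(a, k);
      bvh.e2[3 * t + k] = V(c, k) - V(a, k);
      cent[3 * t + k] = (V(a, k) + V(b, k) + V(c, k)) / 3.0;
    }
  }
  if (nf > 0) build_node(bvh, idx, 0, nf, cent, V, F);
  bvh.order = idx;
  return bvh;
}

inline bool box_hit(const BVHNode& nd, const double* o, const double* inv,
                    double tmax) {
  double t0 = 0.0, t1 = tmax;
  for (int k = 0; k < 3; ++k) {
    double ta = (nd.bmin[k] - o[k]) * inv[k];
    double tb = (nd.bmax[k] - o[k]) * inv[k];
    if (ta > tb) std::swap(ta, tb);
    if (ta > t0) t0 = ta;
    if (tb < t1) t1 = tb;
    if (t0 > t1) return false;
  }
  return true;
}

// Moller-Trumbore; returns hit t or +inf
inline double tri_hit(const BVH& bvh, int t, const double* o, const double* d,
                      double eps) {
  const double* v0 = &bvh.v0[3 * t];
  const double* e1 = &bvh.e1[3 * t];
  const double* e2 = &bvh.e2[3 * t];
  double p0 = d[1] * e2[2] - d[2] * e2[1];
  double p1 = d[2] * e2[0] - d[0] * e2[2];
  double p2 = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p0 + e1[1] * p1 + e1[2] * p2;
  if (std::fabs(det) < kDetEps) return std::numeric_limits<double>::infinity();
  double inv = 1.0 / det;
  double s0 = o[0] - v0[0], s1 = o[1] - v0[1], s2 = o[2] - v0[2];
  double u = (s0 * p0 + s1 * p1 + s2 * p2) * inv;
  if (u < 0.0 || u > 1.0) return std::numeric_limits<double>::infinity();
  double q0 = s1 * e1[2] - s2 * e1[1];
  double q1 = s2 * e1[0] - s0 * e1[2];
  double q2 = s0 * e1[1] - s1 * e1[0];
  double v = (d[0] * q0 + d[1] * q1 + d[2] * q2) * inv;
  if (v < 0.0 || u + v > 1.0) return std::numeric_limits<double>::infinity();
  double t_ = (e2[0] * q0 + e2[1] * q1 + e2[2] * q2) * inv;
  if (t_ <= eps) return std::numeric_limits<double>::infinity();
  return t_;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = "cpp_cast_bvh")]]
Rcpp::NumericVector cpp_cast_bvh(Rcpp::NumericMatrix V, Rcpp::IntegerMatrix F,
                                 Rcpp::NumericVector origin,
                                 Rcpp::NumericMatrix D, double eps) {
  int nr = D.nrow();
  Rcpp::NumericVector out(nr, NA_REAL);
  if (F.nrow() == 0) return out;
  BVH bvh = build_bvh(V, F);
  double o[3] = {origin[0], origin[1], origin[2]};
  std::vector<int> stack;
  stack.reserve(128);
  for (int r = 0; r < nr; ++r) {
    double d[3] = {D(r, 0), D(r, 1), D(r, 2)};
    double inv[3];
    for (int k = 0; k < 3; ++k)
      inv[k] = (d[k] != 0.0) ? 1.0 / d[k]
                             : std::numeric_limits<double>::infinity();
    double best = std::numeric_limits<double>::infinity();
    stack.clear();
    stack.push_back(0);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const BVHNode& nd = bvh.nodes[ni];
      if (!box_hit(nd, o, inv, best)) continue;
      if (nd.left < 0) {
        for (int i = nd.start; i < nd.start + nd.count; ++i) {
          double t = tri_hit(bvh, bvh.order[i], o, d, eps);
          if (t < best) best = t;
        }
      } else {
        stack.push_back(nd.left);
        stack.push_back(nd.right);
      }
    }
    if (std::isfinite(best)) out[r] = best;
  }
  return out;
}
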