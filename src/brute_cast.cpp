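#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

// Exhaustive first-hit ray casting: a plain double loop over every ray and
// every triangle, no spatial acceleration, no code shared with raycast.cpp.
// This is the independent dense-oracle path used to verify the BVH caster.

// [[Rcpp::export(name = "cpp_cast_brute")]]
Rcpp::NumericVector cpp_cast_brute(Rcpp::NumericMatrix V, Rcpp::IntegerMatrix F,
                                   Rcpp::NumericVector origin,
                                   Rcpp::NumericMatrix D, double eps) {
  const int nray = D.nrow();
  const int ntri = F.nrow();
  Rcpp::NumericVector tout(nray, NA_REAL);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  // flatten triangle data once; the cast itself stays an exhaustive loop
  std::vector<double> A(3 * ntri), E1(3 * ntri), E2(3 * ntri);
  for (int f = 0; f < ntri; ++f) {
    const int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      A[3 * f + k] = V(ia, k);
      E1[3 * f + k] = V(ib, k) - V(ia, k);
      E2[3 * f + k] = V(ic, k) - V(ia, k);
    }
  }
  for (int r = 0; r < nray; ++r) {
    const double dx = D(r, 0), dy = D(r, 1), dz = D(r, 2);
    double tbest = std::numeric_limits<double>::infinity();
    for (int f = 0; f < ntri; ++f) {
      const double ax = A[3 * f], ay = A[3 * f + 1], az = A[3 * f + 2];
      const double e1x = E1[3 * f], e1y = E1[3 * f + 1], e1z = E1[3 * f + 2];
      const double e2x = E2[3 * f], e2y = E2[3 * f + 1], e2z = E2[3 * f + 2];
      const double hx = dy * e2z - dz * e2y;
      const double hy = dz * e2x - dx * e2z;
      const double hz = dx * e2y - dy * e2x;
      const double a = e1x * hx + e1y * hy + e1z * hz;
      if (std::fabs(a) < 1e-12) continue;
      const double fi = 1.0 / a;
      const double sx = ox - ax, sy = oy - ay, sz = oz - az;
      const double u = fi * (sx * hx + sy * hy + sz * hz);
      if (u < 0.0 || u > 1.0) continue;
      const double qx = sy * e1z - sz * e1y;
      const double qy = sz * e1x - sx * e1z;
      const double qz = sx * e1y - sy * e1x;
      const double v = fi * (dx * qx + dy * qy + dz * qz);
      if (v < 0.0 || u + v > 1.0) continue;
      const double t = fi * (e2x * qx + e2y * qy + e2z * qz);
      if (t > eps && t < tbest) tbest = t;
    }
    if (std::isfinite(tbest)) tout[r] = tbest;
  }
  return tout;
}
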