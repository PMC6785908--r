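#pragma once
#include <Rcpp.h>
#include <cmath>
#include <cstdint>

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }
inline int clampi(int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); }

inline double smoothstep01(double x) {
  x = clamp01(x);
  return x * x * (3.0 - 2.0 * x);
}

// Closest point on an axis-aligned ellipsoid (semiaxes a, centre cen) to q.
// Solves sum_i (a_i q_i / (a_i^2 + t))^2 = 1 by bisection on the monotone
// Lagrange parameter t in (-min(a_i^2), inf). Signed distance is negative
// inside. Intended for points in or near the shell; interior points beyond
// the evolute on a symmetry axis may resolve to the axial foot point, which
// is adequate for membership queries against the wall.
inline void ellipsoid_foot(const double* q, const double* a, const double* cen,
                           double* foot, double* dist_signed) {
  double p[3], ap[3];
  double amin2 = a[0] * a[0];
  for (int i = 0; i < 3; ++i) {
    p[i] = q[i] - cen[i];
    ap[i] = std::fabs(p[i]);
    double a2 = a[i] * a[i];
    if (a2 < amin2) amin2 = a2;
  }
  double inside_val = 0.0;
  for (int i = 0; i < 3; ++i) {
    double r = p[i] / a[i];
    inside_val += r * r;
  }
  // degenerate centre point: nearest point lies on the smallest semiaxis
  if (ap[0] + ap[1] + ap[2] < 1e-12) {
    int k = 0;
    for (int i = 1; i < 3; ++i) if (a[i] < a[k]) k = i;
    for (int i = 0; i < 3; ++i) foot[i] = cen[i];
    foot[k] = cen[k] + a[k];
    *dist_signed = -a[k];
    return;
  }
  double tlo = -amin2 * (1.0 - 1e-12);
  double amax = std::max(a[0], std::max(a[1], a[2]));
  double nq = std::sqrt(ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2]);
  double thi = amax * nq + amax * amax;
  // ensure g(thi) < 1
  for (int it = 0; it < 60; ++it) {
    double g = 0.0;
    for (int i = 0; i < 3; ++i) {
      double term = a[i] * ap[i] / (a[i] * a[i] + thi);
      g += term * term;
    }
    if (g < 1.0) break;
    thi *= 2.0;
  }
  for (int it = 0; it < 90; ++it) {
    double t = 0.5 * (tlo + thi);
    double g = 0.0;
    for (int i = 0; i < 3; ++i) {
      double term = a[i] * ap[i] / (a[i] * a[i] + t);
      g += term * term;
    }
    if (g > 1.0) tlo = t; else thi = t;
  }
  double t = 0.5 * (tlo + thi);
  double d2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    double e = a[i] * a[i] * p[i] / (a[i] * a[i] + t);
    foot[i] = cen[i] + e;
    double df = p[i] - e;
    d2 += df * df;
  }
  *dist_signed = (inside_val >= 1.0 ? 1.0 : -1.0) * std::sqrt(d2);
}

// trilinear sample of arr (voxel centres at origin + idx*voxel) at world w
inline double trilinear_at(const double* arr, const int* dim,
                           const double* origin, double voxel,
                           const double* w, double outside) {
  double g[3];
  for (int i = 0; i < 3; ++i) g[i] = (w[i] - origin[i]) / voxel;
  int i0[3];
  double f[3];
  for (int i = 0; i < 3; ++i) {
    double fl = std::floor(g[i]);
    i0[i] = (int)fl;
    f[i] = g[i] - fl;
    if (g[i] < -0.5 || g[i] > dim[i] - 0.5) return outside;
  }
  double acc = 0.0;
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double wgt = (dx ? f[0] : 1.0 - f[0]) * (dy ? f[1] : 1.0 - f[1]) *
                     (dz ? f[2] : 1.0 - f[2]);
        if (wgt == 0.0) continue;
        int ix = clampi(i0[0] + dx, 0, dim[0] - 1);
        int iy = clampi(i0[1] + dy, 0, dim[1] - 1);
        int iz = clampi(i0[2] + dz, 0, dim[2] - 1);
        acc += wgt * arr[(size_t)ix + dim[0] * ((size_t)iy + (size_t)dim[1] * iz)];
      }
  return acc;
}

// cubic uniform B-spline basis weights for fractional offset f in [0,1)
inline void bspline_w(double f, double* w) {
  double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (4.0 - 6.0 * f2 + 3.0 * f3) / 6.0;
  w[2] = (1.0 + 3.0 * f + 3.0 * f2 - 3.0 * f3) / 6.0;
  w[3] = f3 / 6.0;
}
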