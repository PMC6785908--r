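// Grid sampling utilities: trilinear interpolation, separable Gaussian
// smoothing, per-label indicator resampling with priority tie-breaks, and
// world-space majority downsampling of label maps.
#include "lvcoreg.h"
using namespace Rcpp;

static void get_dim3(const NumericVector& arr, int* d) {
  IntegerVector dm = arr.attr("dim");
  d[0] = dm[0]; d[1] = dm[1]; d[2] = dm[2];
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, NumericVector origin,
                            double voxel, NumericMatrix pts, double outside) {
  int d[3]; get_dim3(arr, d);
  double o[3] = {origin[0], origin[1], origin[2]};
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double* A = REAL(arr);
  for (R_xlen_t i = 0; i < n; ++i) {
    double w[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    out[i] = trilinear_at(A, d, o, voxel, w, outside);
  }
  return out;
}

// central-difference gradient, units of intensity per mm
// [[Rcpp::export]]
List cpp_central_gradient(NumericVector arr, double voxel) {
  int d[3]; get_dim3(arr, d);
  size_t nx = d[0], ny = d[1], nz = d[2];
  NumericVector gx(arr.size()), gy(arr.size()), gz(arr.size());
  gx.attr("dim") = arr.attr("dim");
  gy.attr("dim") = arr.attr("dim");
  gz.attr("dim") = arr.attr("dim");
  const double* A = REAL(arr);
  double* GX = REAL(gx); double* GY = REAL(gy); double* GZ = REAL(gz);
  for (size_t k = 0; k < nz; ++k)
    for (size_t j = 0; j < ny; ++j)
      for (size_t i = 0; i < nx; ++i) {
        size_t idx = i + nx * (j + ny * k);
        size_t ip = (i + 1 < nx) ? idx + 1 : idx;
        size_t im = (i > 0) ? idx - 1 : idx;
        GX[idx] = (A[ip] - A[im]) / (((i + 1 < nx) + (i > 0)) * voxel);
        size_t jp = (j + 1 < ny) ? idx + nx : idx;
        size_t jm = (j > 0) ? idx - nx : idx;
        GY[idx] = (A[jp] - A[jm]) / (((j + 1 < ny) + (j > 0)) * voxel);
        size_t kp = (k + 1 < nz) ? idx + nx * ny : idx;
        size_t km = (k > 0) ? idx - nx * ny : idx;
        GZ[idx] = (A[kp] - A[km]) / (((k + 1 < nz) + (k > 0)) * voxel);
      }
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

static void smooth_axis(std::vector<double>& buf, double* A, int nx, int ny,
                        int nz, int axis, const std::vector<double>& kern) {
  int r = (int)(kern.size() / 2);
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  size_t total = (size_t)nx * ny * nz;
  buf.assign(A, A + total);
  int len = n[axis];
  size_t st = stride[axis];
  // iterate over all lines along `axis`
  int na = n[(axis + 1) % 3], nb = n[(axis + 2) % 3];
  size_t sa = stride[(axis + 1) % 3], sb = stride[(axis + 2) % 3];
  for (int b = 0; b < nb; ++b)
    for (int a = 0; a < na; ++a) {
      size_t base = a * sa + b * sb;
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -r; k <= r; ++k) {
          int ii = i + k;
          if (ii < 0) ii = -ii;                    // reflect
          if (ii >= len) ii = 2 * len - 2 - ii;
          if (ii < 0) ii = 0;
          acc += kern[k + r] * buf[base + (size_t)ii * st];
        }
        A[base + (size_t)i * st] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, double sigma_vox) {
  int d[3]; get_dim3(arr, d);
  NumericVector out = clone(arr);
  if (sigma_vox <= 0) return out;
  int r = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) {
    kern[k + r] = std::exp(-0.5 * k * k / (sigma_vox * sigma_vox));
    s += kern[k + r];
  }
  for (auto& v : kern) v /= s;
  std::vector<double> buf;
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(buf, REAL(out), d[0], d[1], d[2], axis, kern);
  return out;
}

// Resample a label map at world points: trilinear interpolation of per-label
// indicators, argmax with ties broken by the order of `priority` (first
// entry wins). Points outside the source grid get label 0.
// [[Rcpp::export]]
IntegerVector cpp_label_resample(IntegerVector lab, NumericVector origin,
                                 double voxel, NumericMatrix pts,
                                 IntegerVector priority) {
  IntegerVector dm = lab.attr("dim");
  int d[3] = {dm[0], dm[1], dm[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  R_xlen_t n = pts.nrow();
  IntegerVector out(n);
  const int* L = INTEGER(lab);
  int npr = priority.size();
  std::vector<double> w(npr);
  for (R_xlen_t ip = 0; ip < n; ++ip) {
    double g[3];
    bool outside = false;
    g[0] = (pts(ip, 0) - o[0]) / voxel;
    g[1] = (pts(ip, 1) - o[1]) / voxel;
    g[2] = (pts(ip, 2) - o[2]) / voxel;
    for (int i = 0; i < 3; ++i)
      if (g[i] < -0.5 || g[i] > d[i] - 0.5) outside = true;
    if (outside) { out[ip] = 0; continue; }
    int i0[3]; double f[3];
    for (int i = 0; i < 3; ++i) {
      double fl = std::floor(g[i]);
      i0[i] = (int)fl; f[i] = g[i] - fl;
    }
    std::fill(w.begin(), w.end(), 0.0);
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          double wgt = (dx ? f[0] : 1.0 - f[0]) * (dy ? f[1] : 1.0 - f[1]) *
                       (dz ? f[2] : 1.0 - f[2]);
          if (wgt == 0.0) continue;
          int ix = clampi(i0[0] + dx, 0, d[0] - 1);
          int iy = clampi(i0[1] + dy, 0, d[1] - 1);
          int iz = clampi(i0[2] + dz, 0, d[2] - 1);
          int lv = L[(size_t)ix + d[0] * ((size_t)iy + (size_t)d[1] * iz)];
          for (int q = 0; q < npr; ++q)
            if (priority[q] == lv) { w[q] += wgt; break; }
        }
    int best = 0; double bw = -1.0;
    for (int q = 0; q < npr; ++q)
      if (w[q] > bw + 1e-12) { bw = w[q]; best = priority[q]; }
    out[ip] = best;
  }
  return out;
}

// World-space box downsampling: each fine voxel centre is binned into the
// coarse voxel whose half-open box contains it; coarse label = argmax of
// accumulated per-label fractions with priority tie-break.
// [[Rcpp::export]]
IntegerVector cpp_box_downsample_labels(IntegerVector lab, NumericVector forig,
                                        double fvox, IntegerVector cdim,
                                        NumericVector corig, double cvox,
                                        IntegerVector priority) {
  IntegerVector dm = lab.attr("dim");
  int fd[3] = {dm[0], dm[1], dm[2]};
  int cd[3] = {cdim[0], cdim[1], cdim[2]};
  int npr = priority.size();
  std::vector<int> prank(16, npr);
  for (int q = 0; q < npr; ++q) prank[priority[q]] = q;
  size_t nc = (size_t)cd[0] * cd[1] * cd[2];
  std::vector<std::array<double, 8> > counts(nc);
  for (auto& c : counts) c.fill(0.0);
  const int* L = INTEGER(lab);
  for (int k = 0; k < fd[2]; ++k) {
    double z = forig[2] + k * fvox;
    int ck = (int)std::floor((z - corig[2]) / cvox + 0.5);
    if (ck < 0 || ck >= cd[2]) continue;
    for (int j = 0; j < fd[1]; ++j) {
      double y = forig[1] + j * fvox;
      int cj = (int)std::floor((y - corig[1]) / cvox + 0.5);
      if (cj < 0 || cj >= cd[1]) continue;
      for (int i = 0; i < fd[0]; ++i) {
        double x = forig[0] + i * fvox;
        int ci = (int)std::floor((x - corig[0]) / cvox + 0.5);
        if (ci < 0 || ci >= cd[0]) continue;
        int lv = L[(size_t)i + fd[0] * ((size_t)j + (size_t)fd[1] * k)];
        counts[(size_t)ci + cd[0] * ((size_t)cj + (size_t)cd[1] * ck)][lv] += 1.0;
      }
    }
  }
  IntegerVector out(nc);
  out.attr("dim") = cdim;
  for (size_t c = 0; c < nc; ++c) {
    int best = 0; double bw = -1.0; int brank = npr;
    for (int lv = 0; lv < 8; ++lv) {
      double w = counts[c][lv];
      if (w <= 0.0) continue;
      int rk = prank[lv];
      if (w > bw + 1e-12 || (std::fabs(w - bw) <= 1e-12 && rk < brank)) {
        bw = w; best = lv; brank = rk;
      }
    }
    out[c] = best;
  }
  return out;
}

// y = A x + b (+ cubic B-spline displacement from a control lattice)
// [[Rcpp::export]]
NumericMatrix cpp_transform_points(NumericMatrix pts, NumericMatrix A,
                                   NumericVector b, Nullable<NumericVector> coef_,
                                   NumericVector lat0, double h) {
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  bool ffd = coef_.isNotNull();
  const double* C = nullptr;
  int ld[3] = {0, 0, 0};
  NumericVector coef;
  if (ffd) {
    coef = coef_.get();
    IntegerVector dm = coef.attr("dim");
    ld[0] = dm[0]; ld[1] = dm[1]; ld[2] = dm[2];
    C = REAL(coef);
  }
  for (R_xlen_t ip = 0; ip < n; ++ip) {
    double x[3] = {pts(ip, 0), pts(ip, 1), pts(ip, 2)};
    double y[3];
    for (int r = 0; r < 3; ++r)
      y[r] = A(r, 0) * x[0] + A(r, 1) * x[1] + A(r, 2) * x[2] + b[r];
    if (ffd) {
      double wv[3][4]; int i0[3];
      for (int i = 0; i < 3; ++i) {
        double s = (x[i] - lat0[i]) / h;
        double fl = std::floor(s);
        i0[i] = (int)fl;
        bspline_w(s - fl, wv[i]);
      }
      double u[3] = {0, 0, 0};
      size_t nlat = (size_t)ld[0] * ld[1] * ld[2];
      for (int dz = 0; dz < 4; ++dz) {
        int kz = clampi(i0[2] - 1 + dz, 0, ld[2] - 1);
        for (int dy = 0; dy < 4; ++dy) {
          int ky = clampi(i0[1] - 1 + dy, 0, ld[1] - 1);
          double wyz = wv[1][dy] * wv[2][dz];
          for (int dx = 0; dx < 4; ++dx) {
            int kx = clampi(i0[0] - 1 + dx, 0, ld[0] - 1);
            double w = wv[0][dx] * wyz;
            size_t base = (size_t)kx + ld[0] * ((size_t)ky + (size_t)ld[1] * kz);
            u[0] += w * C[base];
            u[1] += w * C[base + nlat];
            u[2] += w * C[base + 2 * nlat];
          }
        }
      }
      for (int r = 0; r < 3; ++r) y[r] += u[r];
    }
    out(ip, 0) = y[0]; out(ip, 1) = y[1]; out(ip, 2) = y[2];
  }
  return out;
}
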