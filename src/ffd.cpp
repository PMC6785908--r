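// Multi-channel SSD registration metric with optional cubic B-spline FFD,
// plus analytic gradient with respect to the control-point displacements and
// a discrete bending-energy regulariser. The data term is normalised per
// fixed voxel and the bending term per lattice node so the regularisation
// weight is resolution-independent.
#include "lvcoreg.h"
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_bending_energy(NumericVector coef) {
  IntegerVector dm = coef.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t nlat = (size_t)nx * ny * nz;
  const double* C = REAL(coef);
  double e = 0.0;
  for (int d = 0; d < 3; ++d) {
    const double* c = C + d * nlat;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t idx = (size_t)i + nx * ((size_t)j + (size_t)ny * k);
          if (i > 0 && i < nx - 1) {
            double s = c[idx + 1] - 2.0 * c[idx] + c[idx - 1];
            e += s * s;
          }
          if (j > 0 && j < ny - 1) {
            double s = c[idx + nx] - 2.0 * c[idx] + c[idx - nx];
            e += s * s;
          }
          if (k > 0 && k < nz - 1) {
            double s = c[idx + (size_t)nx * ny] - 2.0 * c[idx] +
                       c[idx - (size_t)nx * ny];
            e += s * s;
          }
        }
  }
  return e / (double)nlat;
}

static void bending_grad(const double* C, int nx, int ny, int nz, double scale,
                         double* G) {
  size_t nlat = (size_t)nx * ny * nz;
  size_t sz = (size_t)nx * ny;
  for (int d = 0; d < 3; ++d) {
    const double* c = C + d * nlat;
    double* g = G + d * nlat;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t idx = (size_t)i + nx * ((size_t)j + (size_t)ny * k);
          if (i > 0 && i < nx - 1) {
            double s = 2.0 * scale * (c[idx + 1] - 2.0 * c[idx] + c[idx - 1]);
            g[idx + 1] += s; g[idx] -= 2.0 * s; g[idx - 1] += s;
          }
          if (j > 0 && j < ny - 1) {
            double s = 2.0 * scale * (c[idx + nx] - 2.0 * c[idx] + c[idx - nx]);
            g[idx + nx] += s; g[idx] -= 2.0 * s; g[idx - nx] += s;
          }
          if (k > 0 && k < nz - 1) {
            double s = 2.0 * scale * (c[idx + sz] - 2.0 * c[idx] + c[idx - sz]);
            g[idx + sz] += s; g[idx] -= 2.0 * s; g[idx - sz] += s;
          }
        }
  }
}

// [[Rcpp::export]]
List cpp_reg_cost_grad(NumericMatrix A, NumericVector b,
                       Nullable<NumericVector> coef_, NumericVector lat0,
                       double h, List fixedCh, NumericVector forig, double fvox,
                       List movCh, NumericVector morig, double mvox,
                       Nullable<List> movGrad_, double lambda, bool want_grad) {
  NumericVector f0 = fixedCh[0];
  IntegerVector fdm = f0.attr("dim");
  int fd[3] = {fdm[0], fdm[1], fdm[2]};
  size_t nvox = (size_t)fd[0] * fd[1] * fd[2];
  int nch = fixedCh.size();
  std::vector<const double*> F(nch), M(nch);
  std::vector<const double*> GX(nch), GY(nch), GZ(nch);
  NumericVector m0 = movCh[0];
  IntegerVector mdm = m0.attr("dim");
  int md[3] = {mdm[0], mdm[1], mdm[2]};
  for (int c = 0; c < nch; ++c) {
    NumericVector fc = fixedCh[c]; F[c] = REAL(fc);
    NumericVector mc = movCh[c]; M[c] = REAL(mc);
  }
  List movGrad;
  if (want_grad) {
    movGrad = movGrad_.get();
    for (int c = 0; c < nch; ++c) {
      List g = movGrad[c];
      NumericVector gx = g["gx"], gy = g["gy"], gz = g["gz"];
      GX[c] = REAL(gx); GY[c] = REAL(gy); GZ[c] = REAL(gz);
    }
  }
  bool ffd = coef_.isNotNull();
  NumericVector coef;
  const double* C = nullptr;
  int ld[3] = {1, 1, 1};
  size_t nlat = 1;
  if (ffd) {
    coef = coef_.get();
    IntegerVector dm = coef.attr("dim");
    ld[0] = dm[0]; ld[1] = dm[1]; ld[2] = dm[2];
    nlat = (size_t)ld[0] * ld[1] * ld[2];
    C = REAL(coef);
  }
  NumericVector grad;
  double* G = nullptr;
  if (want_grad) {
    grad = NumericVector(3 * nlat);
    G = REAL(grad);
  }
  double mo[3] = {morig[0], morig[1], morig[2]};
  double cost = 0.0;
  for (int k = 0; k < fd[2]; ++k) {
    double z = forig[2] + k * fvox;
    for (int j = 0; j < fd[1]; ++j) {
      double y0 = forig[1] + j * fvox;
      for (int i = 0; i < fd[0]; ++i) {
        double x[3] = {forig[0] + i * fvox, y0, z};
        double yw[3];
        for (int r = 0; r < 3; ++r)
          yw[r] = A(r, 0) * x[0] + A(r, 1) * x[1] + A(r, 2) * x[2] + b[r];
        double wv[3][4]; int i0[3];
        if (ffd) {
          double u[3] = {0, 0, 0};
          for (int d = 0; d < 3; ++d) {
            double s = (x[d] - lat0[d]) / h;
            double fl = std::floor(s);
            i0[d] = (int)fl;
            bspline_w(s - fl, wv[d]);
          }
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
          for (int r = 0; r < 3; ++r) yw[r] += u[r];
        }
        size_t fidx = (size_t)i + fd[0] * ((size_t)j + (size_t)fd[1] * k);
        double gsum[3] = {0, 0, 0};
        for (int c = 0; c < nch; ++c) {
          double mv = trilinear_at(M[c], md, mo, mvox, yw, 0.0);
          double r = mv - F[c][fidx];
          cost += r * r;
          if (want_grad && ffd) {
            gsum[0] += 2.0 * r * trilinear_at(GX[c], md, mo, mvox, yw, 0.0);
            gsum[1] += 2.0 * r * trilinear_at(GY[c], md, mo, mvox, yw, 0.0);
            gsum[2] += 2.0 * r * trilinear_at(GZ[c], md, mo, mvox, yw, 0.0);
          }
        }
        if (want_grad && ffd &&
            (gsum[0] != 0.0 || gsum[1] != 0.0 || gsum[2] != 0.0)) {
          for (int dz = 0; dz < 4; ++dz) {
            int kz = clampi(i0[2] - 1 + dz, 0, ld[2] - 1);
            for (int dy = 0; dy < 4; ++dy) {
              int ky = clampi(i0[1] - 1 + dy, 0, ld[1] - 1);
              double wyz = wv[1][dy] * wv[2][dz];
              for (int dx = 0; dx < 4; ++dx) {
                int kx = clampi(i0[0] - 1 + dx, 0, ld[0] - 1);
                double w = wv[0][dx] * wyz;
                size_t base = (size_t)kx + ld[0] * ((size_t)ky + (size_t)ld[1] * kz);
                G[base] += w * gsum[0] / (double)nvox;
                G[base + nlat] += w * gsum[1] / (double)nvox;
                G[base + 2 * nlat] += w * gsum[2] / (double)nvox;
              }
            }
          }
        }
      }
    }
  }
  cost /= (double)nvox;
  if (ffd && lambda > 0.0) {
    NumericVector cc = coef;
    cost += lambda * cpp_bending_energy(cc);
    if (want_grad)
      bending_grad(C, ld[0], ld[1], ld[2], lambda / (double)nlat, G);
  }
  if (want_grad)
    return List::create(_["cost"] = cost, _["grad"] = grad);
  return List::create(_["cost"] = cost);
}
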