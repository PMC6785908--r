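// Analytic left-ventricle phantom geometry: membership queries, ground-truth
// transmurality and the forward/inverse shape-change map between the in-vivo
// and ex-vivo conditions. The deformation scales the endocardial ellipsoid
// anisotropically about the cavity centroid and multiplies local wall
// thickness by a region multiplier selected by transmurality, so the inverse
// is available in closed form (one foot-point solve per query).
#include "lvcoreg.h"
using namespace Rcpp;

namespace {

struct Pars {
  double a[3];       // in-vivo endocardial semiaxes (x, y, z=long)
  double t;          // in-vivo wall thickness (mm)
  double zmv;        // mitral-valve truncation plane (z <= zmv kept)
  bool has_scar;
  double phi0, phiw; // scar sector start and angular width (rad)
  double phicw;      // core angular width (rad), measured from phi0
  double zlo, zhi;   // scar longitudinal extent
  double tau_core, tau_rim;
  double band, offset; // thickness-multiplier blend band / outward offset (mm)
  double m_h, m_l, m_hh;
  double S[3];       // ex-vivo/in-vivo cavity scale factors (x, y, z)
  double cz;         // cavity centroid z (scaling centre is (0, 0, cz))
};

Pars parse_pars(const List& P) {
  Pars p;
  NumericVector a = P["a"], S = P["S"];
  for (int i = 0; i < 3; ++i) { p.a[i] = a[i]; p.S[i] = S[i]; }
  p.t = as<double>(P["t"]);
  p.zmv = as<double>(P["zmv"]);
  p.phi0 = as<double>(P["phi0"]);
  p.phiw = as<double>(P["phiw"]);
  p.phicw = as<double>(P["phicw"]);
  p.zlo = as<double>(P["zlo"]);
  p.zhi = as<double>(P["zhi"]);
  p.tau_core = as<double>(P["tau_core"]);
  p.tau_rim = as<double>(P["tau_rim"]);
  p.band = as<double>(P["band"]);
  p.offset = as<double>(P["offset"]);
  p.m_h = as<double>(P["m_h"]);
  p.m_l = as<double>(P["m_l"]);
  p.m_hh = as<double>(P["m_hh"]);
  p.cz = as<double>(P["cz"]);
  p.has_scar = p.phiw > 1e-9 && (p.zhi - p.zlo) > 1e-9;
  return p;
}

// signed angular offset of phi from sector start, in (-pi, pi]
inline double ang_off(double phi, double phi0) {
  double d = phi - phi0;
  while (d <= -M_PI) d += 2.0 * M_PI;
  while (d > M_PI) d -= 2.0 * M_PI;
  return d;
}

// ground-truth transmurality at an endocardial foot point e
inline double tau_at(const Pars& p, const double* e) {
  if (!p.has_scar) return 0.0;
  if (e[2] < p.zlo || e[2] > p.zhi) return 0.0;
  double d = ang_off(std::atan2(e[1], e[0]), p.phi0);
  if (d < 0.0 || d > p.phiw) return 0.0;
  return d <= p.phicw ? p.tau_core : p.tau_rim;
}

// signed depth (mm) into an angular/longitudinal rectangle on the surface
inline double rect_depth(double s, double Ws, double z, double zlo, double zhi) {
  if (s >= 0.0 && s <= Ws && z >= zlo && z <= zhi) {
    double d = std::min(std::min(s, Ws - s), std::min(z - zlo, zhi - z));
    return d;
  }
  double dx = std::max(0.0, std::max(-s, s - Ws));
  double dz = std::max(0.0, std::max(zlo - z, z - zhi));
  return -std::sqrt(dx * dx + dz * dz);
}

// local wall-thickness multiplier, blended across region borders; the
// transition is centred `offset` mm outside each border so the plateau
// multiplier holds right up to (and slightly beyond) the scar edge
inline double mult_at(const Pars& p, const double* e) {
  if (!p.has_scar) return p.m_h;
  double r = std::hypot(e[0], e[1]);
  double u = ang_off(std::atan2(e[1], e[0]), p.phi0);
  double s = u * r;
  double d_scar = rect_depth(s, p.phiw * r, e[2], p.zlo, p.zhi);
  double d_core = rect_depth(s, p.phicw * r, e[2], p.zlo, p.zhi);
  double ws = smoothstep01((d_scar + p.offset) / p.band + 0.5);
  double wc = smoothstep01((d_core + p.offset) / p.band + 0.5);
  return p.m_h + (p.m_l - p.m_h) * ws + (p.m_hh - p.m_l) * wc;
}

const double ZERO3[3] = {0.0, 0.0, 0.0};

// label of an in-vivo point; also reports transmurality of its foot point
inline int label_at(const Pars& p, const double* x, double* tau_out) {
  *tau_out = 0.0;
  if (x[2] > p.zmv + 1e-9) return 0;
  double v = 0.0;
  for (int i = 0; i < 3; ++i) { double r = x[i] / p.a[i]; v += r * r; }
  if (v <= 1.0) return 2;  // cavity
  double e[3], d;
  ellipsoid_foot(x, p.a, ZERO3, e, &d);
  if (d > p.t + 1e-12) return 0;
  double tau = tau_at(p, e);
  *tau_out = tau;
  if (tau > 0.0 && d <= tau * p.t + 1e-12) return 3;  // scar
  return 1;  // myocardium
}

inline void fwd_map(const Pars& p, const double* x, double* q) {
  double c[3] = {0.0, 0.0, p.cz};
  double v = 0.0;
  for (int i = 0; i < 3; ++i) { double r = x[i] / p.a[i]; v += r * r; }
  if (v <= 1.0) {
    for (int i = 0; i < 3; ++i) q[i] = c[i] + p.S[i] * (x[i] - c[i]);
    return;
  }
  double e[3], d;
  ellipsoid_foot(x, p.a, ZERO3, e, &d);
  double ep[3], op[3] = {0.0, 0.0, (1.0 - p.S[2]) * p.cz};
  double ap[3];
  for (int i = 0; i < 3; ++i) {
    ep[i] = c[i] + p.S[i] * (e[i] - c[i]);
    ap[i] = p.S[i] * p.a[i];
  }
  double n[3], nn = 0.0;
  for (int i = 0; i < 3; ++i) {
    n[i] = (ep[i] - op[i]) / (ap[i] * ap[i]);
    nn += n[i] * n[i];
  }
  nn = std::sqrt(nn);
  double m = mult_at(p, e);
  for (int i = 0; i < 3; ++i) q[i] = ep[i] + d * m * n[i] / nn;
}

inline void inv_map(const Pars& p, const double* q, double* x) {
  double c[3] = {0.0, 0.0, p.cz};
  double op[3] = {0.0, 0.0, (1.0 - p.S[2]) * p.cz};
  double ap[3];
  for (int i = 0; i < 3; ++i) ap[i] = p.S[i] * p.a[i];
  double v = 0.0;
  for (int i = 0; i < 3; ++i) {
    double r = (q[i] - op[i]) / ap[i];
    v += r * r;
  }
  if (v <= 1.0) {
    for (int i = 0; i < 3; ++i) x[i] = c[i] + (q[i] - c[i]) / p.S[i];
    return;
  }
  double ep[3], dp;
  ellipsoid_foot(q, ap, op, ep, &dp);
  double e[3];
  for (int i = 0; i < 3; ++i) e[i] = c[i] + (ep[i] - c[i]) / p.S[i];
  double n[3], nn = 0.0;
  for (int i = 0; i < 3; ++i) {
    n[i] = e[i] / (p.a[i] * p.a[i]);
    nn += n[i] * n[i];
  }
  nn = std::sqrt(nn);
  double m = mult_at(p, e);
  for (int i = 0; i < 3; ++i) x[i] = e[i] + (dp / m) * n[i] / nn;
}

}  // namespace

// [[Rcpp::export]]
List cpp_phantom_labels(NumericMatrix pts, List P, bool exvivo) {
  Pars p = parse_pars(P);
  R_xlen_t n = pts.nrow();
  IntegerVector lab(n);
  NumericVector tau(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double x[3];
    if (exvivo) inv_map(p, q, x);
    else { x[0] = q[0]; x[1] = q[1]; x[2] = q[2]; }
    double tv;
    lab[i] = label_at(p, x, &tv);
    tau[i] = tv;
  }
  return List::create(_["label"] = lab, _["tau"] = tau);
}

// [[Rcpp::export]]
NumericMatrix cpp_phantom_map(NumericMatrix pts, List P, bool inverse) {
  Pars p = parse_pars(P);
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double y[3];
    if (inverse) inv_map(p, q, y);
    else fwd_map(p, q, y);
    out(i, 0) = y[0]; out(i, 1) = y[1]; out(i, 2) = y[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_phantom_tau_mult(NumericMatrix pts, List P) {
  Pars p = parse_pars(P);
  R_xlen_t n = pts.nrow();
  NumericVector tau(n), mult(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double e[3], d;
    ellipsoid_foot(q, p.a, ZERO3, e, &d);
    tau[i] = tau_at(p, e);
    mult[i] = mult_at(p, e);
  }
  return List::create(_["tau"] = tau, _["mult"] = mult);
}

// [[Rcpp::export]]
List cpp_ellipsoid_foot(NumericMatrix pts, NumericVector a, NumericVector cen) {
  R_xlen_t n = pts.nrow();
  NumericMatrix foot(n, 3);
  NumericVector dist(n);
  double aa[3] = {a[0], a[1], a[2]};
  double cc[3] = {cen[0], cen[1], cen[2]};
  for (R_xlen_t i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double e[3], d;
    ellipsoid_foot(q, aa, cc, e, &d);
    foot(i, 0) = e[0]; foot(i, 1) = e[1]; foot(i, 2) = e[2];
    dist[i] = d;
  }
  return List::create(_["foot"] = foot, _["dist"] = dist);
}
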