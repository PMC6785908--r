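// Surface extraction by marching tetrahedra (6-tetrahedra cube split with a
// shared main diagonal, vertices welded on cube edges), uniform-weight
// Laplacian smoothing, and a hashed-grid nearest-neighbour lookup.
#include "lvcoreg.h"
#include <unordered_map>
using namespace Rcpp;

namespace {

struct MeshAcc {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based, flattened triples
  std::unordered_map<uint64_t, int> edge_vert;
};

// interpolated vertex on grid edge between global point ids ga < gb
int edge_point(MeshAcc& m, uint64_t ga, uint64_t gb, const double* pa,
               const double* pb, double va, double vb, double iso) {
  if (ga > gb) { std::swap(ga, gb); std::swap(pa, pb); std::swap(va, vb); }
  uint64_t key = ga * 0x100000000ULL ^ gb;
  auto it = m.edge_vert.find(key);
  if (it != m.edge_vert.end()) return it->second;
  double s = (iso - va) / (vb - va);
  s = clamp01(s);
  int id = (int)m.vx.size();
  m.vx.push_back(pa[0] + s * (pb[0] - pa[0]));
  m.vy.push_back(pa[1] + s * (pb[1] - pa[1]));
  m.vz.push_back(pa[2] + s * (pb[2] - pa[2]));
  m.edge_vert[key] = id;
  return id;
}

void do_tet(MeshAcc& m, const uint64_t* gid, double (*P)[3], const double* V,
            const int* t, double iso) {
  int in[4], nin = 0;
  for (int i = 0; i < 4; ++i) {
    in[i] = V[t[i]] > iso;
    nin += in[i];
  }
  if (nin == 0 || nin == 4) return;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) {
    if (in[i]) a[na++] = t[i]; else b[nb++] = t[i];
  }
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? a[0] : b[0];
    const int* others = (nin == 1) ? b : a;
    int p[3];
    for (int i = 0; i < 3; ++i)
      p[i] = edge_point(m, gid[apex], gid[others[i]], P[apex], P[others[i]],
                        V[apex], V[others[i]], iso);
    m.tri.push_back(p[0]); m.tri.push_back(p[1]); m.tri.push_back(p[2]);
  } else {
    // two in, two out: quad split into two triangles
    int p1 = edge_point(m, gid[a[0]], gid[b[0]], P[a[0]], P[b[0]], V[a[0]], V[b[0]], iso);
    int p2 = edge_point(m, gid[a[0]], gid[b[1]], P[a[0]], P[b[1]], V[a[0]], V[b[1]], iso);
    int p3 = edge_point(m, gid[a[1]], gid[b[1]], P[a[1]], P[b[1]], V[a[1]], V[b[1]], iso);
    int p4 = edge_point(m, gid[a[1]], gid[b[0]], P[a[1]], P[b[0]], V[a[1]], V[b[0]], iso);
    m.tri.push_back(p1); m.tri.push_back(p2); m.tri.push_back(p3);
    m.tri.push_back(p1); m.tri.push_back(p3); m.tri.push_back(p4);
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector field, NumericVector origin,
                        double voxel, double iso) {
  IntegerVector dm = field.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  const double* F = REAL(field);
  // cube corner offsets
  static const int CO[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                               {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra sharing diagonal 0-6
  static const int TETS[6][4] = {{0,1,2,6},{0,2,3,6},{0,3,7,6},
                                 {0,7,4,6},{0,4,5,6},{0,5,1,6}};
  MeshAcc m;
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double V[8], P[8][3];
        uint64_t gid[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CO[c][0], jj = j + CO[c][1], kk = k + CO[c][2];
          size_t idx = (size_t)ii + nx * ((size_t)jj + (size_t)ny * kk);
          V[c] = F[idx];
          gid[c] = idx;
          P[c][0] = origin[0] + ii * voxel;
          P[c][1] = origin[1] + jj * voxel;
          P[c][2] = origin[2] + kk * voxel;
          if (V[c] > iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int tq = 0; tq < 6; ++tq)
          do_tet(m, gid, P, V, TETS[tq], iso);
      }
  int nv = (int)m.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = m.vx[i]; verts(i, 1) = m.vy[i]; verts(i, 2) = m.vz[i];
  }
  int nt = (int)m.tri.size() / 3;
  IntegerMatrix tris(nt, 3);
  for (int i = 0; i < nt; ++i) {
    tris(i, 0) = m.tri[3 * i] + 1;      // 1-based for R
    tris(i, 1) = m.tri[3 * i + 1] + 1;
    tris(i, 2) = m.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["triangles"] = tris);
}

// [[Rcpp::export]]
NumericMatrix cpp_laplacian_smooth(NumericMatrix verts, IntegerMatrix tris,
                                   int iters, double lambda) {
  int nv = verts.nrow(), nt = tris.nrow();
  std::vector<double> x(nv), y(nv), z(nv);
  for (int i = 0; i < nv; ++i) {
    x[i] = verts(i, 0); y[i] = verts(i, 1); z[i] = verts(i, 2);
  }
  std::vector<double> sx(nv), sy(nv), sz(nv);
  std::vector<double> deg(nv);
  for (int it = 0; it < iters; ++it) {
    std::fill(sx.begin(), sx.end(), 0.0);
    std::fill(sy.begin(), sy.end(), 0.0);
    std::fill(sz.begin(), sz.end(), 0.0);
    std::fill(deg.begin(), deg.end(), 0.0);
    for (int t = 0; t < nt; ++t) {
      int a = tris(t, 0) - 1, b = tris(t, 1) - 1, c = tris(t, 2) - 1;
      const int e[3][2] = {{a, b}, {b, c}, {c, a}};
      for (int q = 0; q < 3; ++q) {
        int u = e[q][0], v = e[q][1];
        sx[u] += x[v]; sy[u] += y[v]; sz[u] += z[v]; deg[u] += 1.0;
        sx[v] += x[u]; sy[v] += y[u]; sz[v] += z[u]; deg[v] += 1.0;
      }
    }
    for (int i = 0; i < nv; ++i) {
      if (deg[i] <= 0) continue;
      x[i] += lambda * (sx[i] / deg[i] - x[i]);
      y[i] += lambda * (sy[i] / deg[i] - y[i]);
      z[i] += lambda * (sz[i] / deg[i] - z[i]);
    }
  }
  NumericMatrix out(nv, 3);
  for (int i = 0; i < nv; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return out;
}

// nearest reference point index (1-based) for each query point; exact, via a
// dense uniform grid (counting sort) with expanding ring search;
// ties -> lowest index
// [[Rcpp::export]]
IntegerVector cpp_nn_index(NumericMatrix query_, NumericMatrix ref_) {
  int nq = query_.nrow(), nr = ref_.nrow();
  IntegerVector out(nq);
  if (nr == 0) return out;
  std::vector<double> query(3 * (size_t)nq), ref(3 * (size_t)nr);
  for (int i = 0; i < nq; ++i)
    for (int d = 0; d < 3; ++d) query[3 * (size_t)i + d] = query_(i, d);
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) ref[3 * (size_t)i + d] = ref_(i, d);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], ref[3 * (size_t)i + d]);
      hi[d] = std::max(hi[d], ref[3 * (size_t)i + d]);
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-6});
  double cell = ext / 48.0;
  int ncell[3];
  for (int d = 0; d < 3; ++d)
    ncell[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / cell) + 1);
  auto cell_of = [&](double v, int d) {
    return clampi((int)std::floor((v - lo[d]) / cell), 0, ncell[d] - 1);
  };
  size_t ntot = (size_t)ncell[0] * ncell[1] * ncell[2];
  auto cidx = [&](int a, int b, int c) {
    return (size_t)a + ncell[0] * ((size_t)b + (size_t)ncell[1] * c);
  };
  // counting sort of reference points into cells
  std::vector<int> count(ntot + 1, 0), order(nr);
  std::vector<size_t> cell_id(nr);
  for (int i = 0; i < nr; ++i) {
    cell_id[i] = cidx(cell_of(ref[3 * (size_t)i], 0),
                      cell_of(ref[3 * (size_t)i + 1], 1),
                      cell_of(ref[3 * (size_t)i + 2], 2));
    ++count[cell_id[i] + 1];
  }
  for (size_t c = 0; c < ntot; ++c) count[c + 1] += count[c];
  std::vector<int> fill(count.begin(), count.end());
  for (int i = 0; i < nr; ++i) order[fill[cell_id[i]]++] = i;
  // order[] within a cell is ascending in i, so lowest index wins on ties
  int maxring = std::max({ncell[0], ncell[1], ncell[2]});
  for (int q = 0; q < nq; ++q) {
    double p[3] = {query[3 * (size_t)q], query[3 * (size_t)q + 1],
                   query[3 * (size_t)q + 2]};
    int cq[3] = {cell_of(p[0], 0), cell_of(p[1], 1), cell_of(p[2], 2)};
    int best = -1;
    double bd = R_PosInf;
    for (int ring = 0; ring <= maxring; ++ring) {
      if (best >= 0 && bd <= (double)(ring - 1) * cell) break;
      int zlo = std::max(cq[2] - ring, 0), zhi = std::min(cq[2] + ring, ncell[2] - 1);
      int ylo = std::max(cq[1] - ring, 0), yhi = std::min(cq[1] + ring, ncell[1] - 1);
      int xlo = std::max(cq[0] - ring, 0), xhi = std::min(cq[0] + ring, ncell[0] - 1);
      for (int cz = zlo; cz <= zhi; ++cz)
        for (int cy = ylo; cy <= yhi; ++cy)
          for (int cx = xlo; cx <= xhi; ++cx) {
            int ringpos = std::max({std::abs(cx - cq[0]), std::abs(cy - cq[1]),
                                    std::abs(cz - cq[2])});
            if (ringpos != ring) continue;
            size_t c = cidx(cx, cy, cz);
            for (int s = count[c]; s < count[c + 1]; ++s) {
              int i = order[s];
              const double* r = &ref[3 * (size_t)i];
              double dxp = r[0] - p[0], dyp = r[1] - p[1], dzp = r[2] - p[2];
              double d = std::sqrt(dxp * dxp + dyp * dyp + dzp * dzp);
              if (d < bd - 1e-15 || (std::fabs(d - bd) <= 1e-15 && i < best)) {
                bd = d; best = i;
              }
            }
          }
    }
    out[q] = best + 1;
  }
  return out;
}
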