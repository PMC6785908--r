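// 3D connected components with 6/18/26 connectivity (breadth-first search).
#include "lvcoreg.h"
#include <queue>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_connected_components(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  size_t n = (size_t)nx * ny * nz;
  const int* M = INTEGER(mask);
  IntegerVector out(n);
  out.attr("dim") = dm;
  int* L = INTEGER(out);
  std::fill(L, L + n, 0);
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int o = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (o == 0) continue;
        if (connectivity == 6 && o > 1) continue;
        if (connectivity == 18 && o > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int comp = 0;
  std::queue<size_t> q;
  for (size_t s = 0; s < n; ++s) {
    if (!M[s] || L[s]) continue;
    ++comp;
    L[s] = comp;
    q.push(s);
    while (!q.empty()) {
      size_t cur = q.front(); q.pop();
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((size_t)nx * ny);
      for (const auto& o : offs) {
        int ii = ci + o[0], jj = cj + o[1], kk = ck + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t idx = (size_t)ii + nx * ((size_t)jj + (size_t)ny * kk);
        if (M[idx] && !L[idx]) { L[idx] = comp; q.push(idx); }
      }
    }
  }
  return out;
}
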