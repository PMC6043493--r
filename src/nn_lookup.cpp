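#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact nearest-candidate search in pre-scaled (R1, R2, PD) space using a
// uniform spatial hash over the candidate cloud. Ties in distance (within a
// small absolute tolerance) resolve to the candidate with the lower myelin
// fraction, which keeps the projection deterministic and conservative.
//
// cand: m x 3 scaled candidate triples, sorted by ascending v_my on the R side
// vmy:  m myelin fractions matching cand rows
// query: q x 3 scaled query triples (finite)
// returns 1-based index into cand rows of the nearest candidate per query
// [[Rcpp::export]]
IntegerVector nn_lookup_cpp(NumericMatrix cand, NumericVector vmy,
                            NumericMatrix query) {
  const int m = cand.nrow(), q = query.nrow();
  if (m == 0) stop("empty candidate set");
  IntegerVector out(q);

  // bounding box of candidates
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = hi[d] = cand(0, d);
    for (int i = 1; i < m; ++i) {
      const double v = cand(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-6);
  // cubic cells, ~4 candidates per occupied cell on average
  double h = std::cbrt(vol / std::max(m / 4, 1));
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
    nc[d] = std::min(nc[d], 256);
  }
  const long ncell = (long)nc[0] * nc[1] * nc[2];

  std::vector<int> cellof(m);
  std::vector<int> count(ncell + 1, 0);
  auto cell_index = [&](double x, double y, double z, int* c3) {
    double p[3] = {x, y, z};
    for (int d = 0; d < 3; ++d) {
      int k = (int)std::floor((p[d] - lo[d]) / h);
      if (k < 0) k = 0;
      if (k >= nc[d]) k = nc[d] - 1;
      c3[d] = k;
    }
    return ((long)c3[2] * nc[1] + c3[1]) * nc[0] + c3[0];
  };
  int c3[3];
  for (int i = 0; i < m; ++i) {
    long c = cell_index(cand(i, 0), cand(i, 1), cand(i, 2), c3);
    cellof[i] = (int)c;
    ++count[c + 1];
  }
  for (long c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(m);
  {
    std::vector<int> cursor(count.begin(), count.end() - 1);
    for (int i = 0; i < m; ++i) bucket[cursor[cellof[i]]++] = i;
  }

  const double tie_tol = 1e-12;
  for (int iq = 0; iq < q; ++iq) {
    const double qx = query(iq, 0), qy = query(iq, 1), qz = query(iq, 2);
    int qc[3];
    cell_index(qx, qy, qz, qc);
    double best_d2 = R_PosInf, best_vmy = R_PosInf;
    int best = -1;
    const int rmax = std::max(std::max(nc[0], nc[1]), nc[2]);
    for (int r = 0; ; ++r) {
      bool any_cell = false;
      const int x0 = qc[0] - r, x1 = qc[0] + r;
      const int y0 = qc[1] - r, y1 = qc[1] + r;
      const int z0 = qc[2] - r, z1 = qc[2] + r;
      for (int z = z0; z <= z1; ++z) {
        if (z < 0 || z >= nc[2]) continue;
        for (int y = y0; y <= y1; ++y) {
          if (y < 0 || y >= nc[1]) continue;
          for (int x = x0; x <= x1; ++x) {
            if (x < 0 || x >= nc[0]) continue;
            // only the shell at Chebyshev radius r
            if (r > 0 && x != x0 && x != x1 && y != y0 && y != y1 &&
                z != z0 && z != z1)
              continue;
            any_cell = true;
            const long c = ((long)z * nc[1] + y) * nc[0] + x;
            for (int t = count[c]; t < count[c + 1]; ++t) {
              const int i = bucket[t];
              const double dx = cand(i, 0) - qx;
              const double dy = cand(i, 1) - qy;
              const double dz = cand(i, 2) - qz;
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best_d2 - tie_tol) {
                best_d2 = d2; best = i; best_vmy = vmy[i];
              } else if (d2 <= best_d2 + tie_tol && vmy[i] < best_vmy) {
                best = i; best_vmy = vmy[i];
              }
            }
          }
        }
      }
      // any unexamined candidate sits in a shell > r, hence at distance
      // >= r*h from the query's cell region; safe to stop once the best
      // found distance is within that bound
      if (best >= 0 && std::sqrt(best_d2) <= r * h) break;
      if (r > rmax && best >= 0) break;
      if (r > rmax && !any_cell) break;
    }
    out[iq] = best + 1;
  }
  return out;
}
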