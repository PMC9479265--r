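#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Nearest reference point for each query point on a planar metric grid.
//
// Uniform-grid bucket index over the reference points with an expanding
// ring search. Ties at exactly equal squared distance resolve to the
// lowest reference index, so callers wanting a tie-break on an id must
// pass reference points sorted by that id.
//
// Returns 1-based indices into (px, py).
// [[Rcpp::export(name = ".nearest_point_index")]]
IntegerVector nearest_point_index(NumericVector qx, NumericVector qy,
                                  NumericVector px, NumericVector py) {
  const int nq = qx.size();
  const int np = px.size();
  if (np == 0) stop("no reference points");
  IntegerVector out(nq);

  // bounding box of reference points
  double x0 = px[0], x1 = px[0], y0 = py[0], y1 = py[0];
  for (int i = 1; i < np; ++i) {
    if (px[i] < x0) x0 = px[i];
    if (px[i] > x1) x1 = px[i];
    if (py[i] < y0) y0 = py[i];
    if (py[i] > y1) y1 = py[i];
  }
  int side = (int)std::floor(std::sqrt((double)np));
  if (side < 1) side = 1;
  if (side > 1024) side = 1024;
  const int nx = side, ny = side;
  double cw = (x1 - x0) / nx, ch = (y1 - y0) / ny;
  if (cw <= 0) cw = 1.0;
  if (ch <= 0) ch = 1.0;
  const double mincell = std::min(cw, ch);

  // CSR buckets
  std::vector<int> cell(np), cnt(nx * ny + 1, 0);
  for (int i = 0; i < np; ++i) {
    int cx = (int)((px[i] - x0) / cw); if (cx >= nx) cx = nx - 1; if (cx < 0) cx = 0;
    int cy = (int)((py[i] - y0) / ch); if (cy >= ny) cy = ny - 1; if (cy < 0) cy = 0;
    cell[i] = cy * nx + cx;
    ++cnt[cell[i] + 1];
  }
  for (int c = 0; c < nx * ny; ++c) cnt[c + 1] += cnt[c];
  std::vector<int> bucket(np), fill(cnt.begin(), cnt.end() - 1);
  for (int i = 0; i < np; ++i) bucket[fill[cell[i]]++] = i;

  for (int q = 0; q < nq; ++q) {
    const double x = qx[q], y = qy[q];
    int ci = (int)((x - x0) / cw); if (ci >= nx) ci = nx - 1; if (ci < 0) ci = 0;
    int cj = (int)((y - y0) / ch); if (cj >= ny) cj = ny - 1; if (cj < 0) cj = 0;
    // distance from query to its clamped cell (0 when inside the grid)
    double cxlo = x0 + ci * cw, cxhi = x0 + (ci + 1) * cw;
    double cylo = y0 + cj * ch, cyhi = y0 + (cj + 1) * ch;
    double dcx = (x < cxlo) ? cxlo - x : (x > cxhi ? x - cxhi : 0.0);
    double dcy = (y < cylo) ? cylo - y : (y > cyhi ? y - cyhi : 0.0);
    const double dclamp = std::sqrt(dcx * dcx + dcy * dcy);

    double best2 = R_PosInf;
    int besti = -1;
    const int kmax = std::max(nx, ny);
    for (int k = 0; k <= kmax; ++k) {
      if (besti >= 0) {
        // any point in a ring-k cell is at least (k-1)*mincell from the
        // clamped cell, hence at least that minus dclamp from the query
        double lb = (k - 1) * mincell - dclamp;
        if (lb > 0 && lb * lb > best2) break;
      }
      const int ilo = std::max(0, ci - k), ihi = std::min(nx - 1, ci + k);
      const int jlo = std::max(0, cj - k), jhi = std::min(ny - 1, cj + k);
      for (int j = jlo; j <= jhi; ++j) {
        const bool jedge = (j == cj - k || j == cj + k);
        for (int i = ilo; i <= ihi; ++i) {
          if (!jedge && i != ci - k && i != ci + k) continue; // ring only
          // box distance prune
          double bxlo = x0 + i * cw, bxhi = bxlo + cw;
          double bylo = y0 + j * ch, byhi = bylo + ch;
          double bx = (x < bxlo) ? bxlo - x : (x > bxhi ? x - bxhi : 0.0);
          double by = (y < bylo) ? bylo - y : (y > byhi ? y - byhi : 0.0);
          if (besti >= 0 && bx * bx + by * by > best2) continue;
          const int c = j * nx + i;
          for (int b = cnt[c]; b < cnt[c + 1]; ++b) {
            const int p = bucket[b];
            const double dx = px[p] - x, dy = py[p] - y;
            const double d2 = dx * dx + dy * dy;
            if (d2 < best2 || (d2 == best2 && p < besti)) {
              best2 = d2;
              besti = p;
            }
          }
        }
      }
    }
    out[q] = besti + 1;
  }
  return out;
}
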