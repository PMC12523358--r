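#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate radially symmetric triangular (conical) kernels onto a grid.
// Grid rows index y south->north, columns x west->east; cell (r, c) centre is
// (x0 + (c + 0.5) * cell, y0 + (r + 0.5) * cell) with 0-based r, c.
// Each point deposits weight w[i] of total mass spread as
// K(d) = 3 / (pi h^2) * (1 - d / h) for d < h. Values are densities (m^-2).
// [[Rcpp::export]]
NumericMatrix kde_accumulate(int nrow, int ncol, double x0, double y0,
                             double cell, NumericVector px, NumericVector py,
                             double h, NumericVector w) {
  NumericMatrix out(nrow, ncol);
  const double norm = 3.0 / (M_PI * h * h);
  const int n = px.size();
  for (int i = 0; i < n; ++i) {
    const double xi = px[i], yi = py[i], wi = w[i];
    if (wi == 0.0) continue;
    int c0 = (int)std::floor((xi - h - x0) / cell);
    int c1 = (int)std::ceil((xi + h - x0) / cell);
    int r0 = (int)std::floor((yi - h - y0) / cell);
    int r1 = (int)std::ceil((yi + h - y0) / cell);
    if (c0 < 0) c0 = 0;
    if (r0 < 0) r0 = 0;
    if (c1 > ncol - 1) c1 = ncol - 1;
    if (r1 > nrow - 1) r1 = nrow - 1;
    for (int c = c0; c <= c1; ++c) {
      const double dx = x0 + (c + 0.5) * cell - xi;
      for (int r = r0; r <= r1; ++r) {
        const double dy = y0 + (r + 0.5) * cell - yi;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < h) out(r, c) += wi * norm * (1.0 - d / h);
      }
    }
  }
  return out;
}

// Bin weighted points into grid cells (occupancy counting); returns per-cell
// totals divided by cell area, i.e. a density surface on the same grid
// convention as kde_accumulate. Points outside the grid are dropped.
// [[Rcpp::export]]
NumericMatrix bin_accumulate(int nrow, int ncol, double x0, double y0,
                             double cell, NumericVector px, NumericVector py,
                             NumericVector w) {
  NumericMatrix out(nrow, ncol);
  const int n = px.size();
  const double inv_area = 1.0 / (cell * cell);
  for (int i = 0; i < n; ++i) {
    int c = (int)std::floor((px[i] - x0) / cell);
    int r = (int)std::floor((py[i] - y0) / cell);
    if (c < 0 || c >= ncol || r < 0 || r >= nrow) continue;
    out(r, c) += w[i] * inv_area;
  }
  return out;
}
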