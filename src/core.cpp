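#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Uniform-cell spatial hash over a 2-D point set. Post-thinning populations
// have a hard minimum spacing, so occupancy per cell stays bounded and both
// queries below run in roughly linear time.
namespace {

struct CellGrid {
  int nx, ny;
  double x0, y0, cell;
  std::vector<std::vector<int> > bins;

  CellGrid(const NumericVector& x, const NumericVector& y, double cell_) {
    cell = cell_;
    x0 = *std::min_element(x.begin(), x.end());
    y0 = *std::min_element(y.begin(), y.end());
    double x1 = *std::max_element(x.begin(), x.end());
    double y1 = *std::max_element(y.begin(), y.end());
    nx = std::max(1, (int)std::floor((x1 - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((y1 - y0) / cell) + 1);
    bins.resize((size_t)nx * (size_t)ny);
    for (int i = 0; i < x.size(); ++i)
      bins[idx(cx(x[i]), cy(y[i]))].push_back(i);
  }
  inline int cx(double v) const {
    int c = (int)std::floor((v - x0) / cell);
    return c < 0 ? 0 : (c >= nx ? nx - 1 : c);
  }
  inline int cy(double v) const {
    int c = (int)std::floor((v - y0) / cell);
    return c < 0 ? 0 : (c >= ny ? ny - 1 : c);
  }
  inline size_t idx(int gx, int gy) const {
    return (size_t)gy * (size_t)nx + (size_t)gx;
  }
};

} // namespace

// Indices (1-based) of the nearest and second-nearest *other* point for each
// point; ties broken by lowest index. Column entries are 0 when no such
// neighbour exists (n < 2 or n < 3).
// [[Rcpp::export]]
IntegerMatrix nearest_two_cpp(NumericVector x, NumericVector y, double cell) {
  int n = x.size();
  IntegerMatrix out(n, 2);
  if (n < 2) return out;
  CellGrid g(x, y, cell);
  int maxring = g.nx + g.ny;

  for (int i = 0; i < n; ++i) {
    double d1 = R_PosInf, d2 = R_PosInf;
    int j1 = -1, j2 = -1;
    int ci = g.cx(x[i]), cj = g.cy(y[i]);
    for (int r = 0; r <= maxring; ++r) {
      int gx_lo = std::max(0, ci - r), gx_hi = std::min(g.nx - 1, ci + r);
      int gy_lo = std::max(0, cj - r), gy_hi = std::min(g.ny - 1, cj + r);
      for (int gx = gx_lo; gx <= gx_hi; ++gx) {
        for (int gy = gy_lo; gy <= gy_hi; ++gy) {
          if (std::max(std::abs(gx - ci), std::abs(gy - cj)) != r) continue;
          const std::vector<int>& pts = g.bins[g.idx(gx, gy)];
          for (size_t k = 0; k < pts.size(); ++k) {
            int j = pts[k];
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            double dd = dx * dx + dy * dy;
            if (dd < d1 || (dd == d1 && j < j1)) {
              d2 = d1; j2 = j1; d1 = dd; j1 = j;
            } else if (j != j1 && (dd < d2 || (dd == d2 && j < j2))) {
              d2 = dd; j2 = j;
            }
          }
        }
      }
      // Unscanned cells lie at Chebyshev ring >= r+1, hence at distance
      // >= r*cell from point i; strict inequality keeps index tie-breaks
      // exact at the boundary.
      double lb = (double)r * g.cell;
      if (j2 >= 0 && d2 < lb * lb) break;
    }
    out(i, 0) = j1 + 1;
    out(i, 1) = j2 + 1;
  }
  return out;
}

// Greedy thinning in the supplied (1-based) order: a point is kept iff no
// already-kept point lies strictly within `radius` of it.
// [[Rcpp::export]]
LogicalVector thin_cpp(NumericVector x, NumericVector y, IntegerVector order,
                       double radius) {
  int n = x.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  CellGrid g(x, y, radius);
  std::vector<std::vector<int> > kept((size_t)g.nx * (size_t)g.ny);
  double r2 = radius * radius;

  for (int k = 0; k < n; ++k) {
    int i = order[k] - 1;
    int ci = g.cx(x[i]), cj = g.cy(y[i]);
    bool ok = true;
    for (int gx = std::max(0, ci - 1); ok && gx <= std::min(g.nx - 1, ci + 1); ++gx) {
      for (int gy = std::max(0, cj - 1); ok && gy <= std::min(g.ny - 1, cj + 1); ++gy) {
        const std::vector<int>& pts = kept[g.idx(gx, gy)];
        for (size_t m = 0; m < pts.size(); ++m) {
          double dx = x[pts[m]] - x[i], dy = y[pts[m]] - y[i];
          if (dx * dx + dy * dy < r2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      keep[i] = true;
      kept[g.idx(ci, cj)].push_back(i);
    }
  }
  return keep;
}

// Exact mean pairwise Euclidean distance of a point set.
// [[Rcpp::export]]
double mean_pairdist_cpp(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n < 2) return NA_REAL;
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      s += std::sqrt(dx * dx + dy * dy);
    }
  }
  return s / ((double)n * (n - 1) / 2.0);
}
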