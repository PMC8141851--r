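#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Uniform-grid spatial binning with intrusive linked lists (head/next),
// so rebuilding each relaxation sweep costs two flat array fills and no
// per-bin allocations. Bin size equals the interaction radius: neighbor
// queries only touch the 3x3 bin block.
struct BinGrid {
  double xmin, ymin, cell;
  int nx, ny;
  std::vector<int> head, nxt;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             double cell_size) {
    int n = (int)x.size();
    cell = cell_size;
    xmin = R_PosInf; ymin = R_PosInf;
    double xmax = R_NegInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (x[i] < xmin) xmin = x[i];
      if (x[i] > xmax) xmax = x[i];
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    nx = (int)std::floor((xmax - xmin) / cell) + 1;
    ny = (int)std::floor((ymax - ymin) / cell) + 1;
    if (nx < 1) nx = 1;
    if (ny < 1) ny = 1;
    head.assign((size_t)nx * ny, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int b = index_of(x[i], y[i]);
      nxt[i] = head[b];
      head[b] = i;
    }
  }

  int index_of(double px, double py) const {
    int bx = (int)std::floor((px - xmin) / cell);
    int by = (int)std::floor((py - ymin) / cell);
    if (bx < 0) bx = 0; if (bx >= nx) bx = nx - 1;
    if (by < 0) by = 0; if (by >= ny) by = ny - 1;
    return by * nx + bx;
  }
};

static double measure_residual(const std::vector<double>& x,
                               const std::vector<double>& y,
                               double d0, BinGrid& grid) {
  grid.build(x, y, d0);
  double worst = 0.0;
  int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    int bx = (int)std::floor((x[i] - grid.xmin) / grid.cell);
    int by = (int)std::floor((y[i] - grid.ymin) / grid.cell);
    for (int dbx = -1; dbx <= 1; ++dbx)
      for (int dby = -1; dby <= 1; ++dby) {
        int ox = bx + dbx, oy = by + dby;
        if (ox < 0 || oy < 0 || ox >= grid.nx || oy >= grid.ny) continue;
        for (int j = grid.head[(size_t)oy * grid.nx + ox]; j >= 0;
             j = grid.nxt[j]) {
          if (j <= i) continue;
          double dxv = x[j] - x[i], dyv = y[j] - y[i];
          double d = std::sqrt(dxv * dxv + dyv * dyv);
          if (d0 - d > worst) worst = d0 - d;
        }
      }
  }
  return worst;
}

// Iterative pairwise displacement (Gauss-Seidel sweeps over neighbor
// pairs, over-relaxed by beta) until the post-sweep residual overlap
// falls below tol_frac * r, or max_iter sweeps have run. Cells are
// circles of common radius r.
// [[Rcpp::export]]
List relax_cells_cpp(NumericVector x, NumericVector y, double r,
                     double tol_frac, int max_iter, double beta = 1.0) {
  int n = x.size();
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end());
  const double d0 = 2.0 * r;         // rest center distance
  const double tol = tol_frac * r;
  double max_overlap = 0.0;
  int sweeps = 0;

  if (n < 2) {
    return List::create(_["x"] = x, _["y"] = y,
                        _["sweeps"] = 0, _["max_overlap"] = 0.0);
  }

  BinGrid grid, after;
  double residual = R_PosInf;
  for (sweeps = 0; sweeps < max_iter; ++sweeps) {
    grid.build(xx, yy, d0);
    max_overlap = 0.0;
    for (int i = 0; i < n; ++i) {
      int bx = (int)std::floor((xx[i] - grid.xmin) / grid.cell);
      int by = (int)std::floor((yy[i] - grid.ymin) / grid.cell);
      for (int dbx = -1; dbx <= 1; ++dbx) {
        for (int dby = -1; dby <= 1; ++dby) {
          int ox = bx + dbx, oy = by + dby;
          if (ox < 0 || oy < 0 || ox >= grid.nx || oy >= grid.ny) continue;
          for (int j = grid.head[(size_t)oy * grid.nx + ox]; j >= 0;
               j = grid.nxt[j]) {
            if (j <= i) continue;  // each unordered pair once
            double dxv = xx[j] - xx[i];
            double dyv = yy[j] - yy[i];
            double d2 = dxv * dxv + dyv * dyv;
            if (d2 >= d0 * d0) continue;
            double d = std::sqrt(d2);
            double overlap = d0 - d;
            if (overlap > max_overlap) max_overlap = overlap;
            double ux, uy;
            if (d > 1e-12) {
              ux = dxv / d; uy = dyv / d;
            } else {
              // coincident centers: deterministic push along x
              ux = 1.0; uy = 0.0;
            }
            double half = 0.5 * beta * overlap;
            xx[i] -= ux * half; yy[i] -= uy * half;
            xx[j] += ux * half; yy[j] += uy * half;
          }
        }
      }
    }
    // converge on the post-sweep residual, not the overlaps seen (and
    // already displaced) during the sweep; skip the measurement pass
    // while the sweep itself still found large overlaps
    if (max_overlap >= tol) continue;
    residual = measure_residual(xx, yy, d0, after);
    if (residual < tol) { ++sweeps; break; }
  }
  if (!(residual < R_PosInf)) residual = measure_residual(xx, yy, d0, after);

  return List::create(_["x"] = NumericVector(xx.begin(), xx.end()),
                      _["y"] = NumericVector(yy.begin(), yy.end()),
                      _["sweeps"] = sweeps, _["max_overlap"] = residual);
}

// For each donor index (1-based), pick one uniformly random neighbor whose
// center lies within max_dist (excluding the donor itself). Returns a
// 1-based recipient index per donor, or NA when the donor has no neighbor.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector pick_neighbors_cpp(NumericVector x, NumericVector y,
                                 IntegerVector donors, double max_dist) {
  int nd = donors.size();
  IntegerVector out(nd, NA_INTEGER);
  if (x.size() < 2 || nd == 0) return out;
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end());
  BinGrid grid;
  grid.build(xx, yy, max_dist);
  double md2 = max_dist * max_dist;
  std::vector<int> cand;
  for (int k = 0; k < nd; ++k) {
    int i = donors[k] - 1;
    cand.clear();
    int bx = (int)std::floor((xx[i] - grid.xmin) / grid.cell);
    int by = (int)std::floor((yy[i] - grid.ymin) / grid.cell);
    if (bx < 0) bx = 0; if (bx >= grid.nx) bx = grid.nx - 1;
    if (by < 0) by = 0; if (by >= grid.ny) by = grid.ny - 1;
    for (int dbx = -1; dbx <= 1; ++dbx)
      for (int dby = -1; dby <= 1; ++dby) {
        int ox = bx + dbx, oy = by + dby;
        if (ox < 0 || oy < 0 || ox >= grid.nx || oy >= grid.ny) continue;
        for (int j = grid.head[(size_t)oy * grid.nx + ox]; j >= 0;
             j = grid.nxt[j]) {
          if (j == i) continue;
          double dxv = xx[j] - xx[i], dyv = yy[j] - yy[i];
          if (dxv * dxv + dyv * dyv <= md2) cand.push_back(j);
        }
      }
    if (!cand.empty()) {
      int pick = (int)std::floor(unif_rand() * cand.size());
      if (pick >= (int)cand.size()) pick = cand.size() - 1;
      out[k] = cand[pick] + 1;
    }
  }
  return out;
}

// Largest pairwise overlap (d0 - distance, clamped at 0) in the colony.
// [[Rcpp::export]]
double max_overlap_cpp(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  if (n < 2) return 0.0;
  std::vector<double> xx(x.begin(), x.end()), yy(y.begin(), y.end());
  BinGrid grid;
  return measure_residual(xx, yy, 2.0 * r, grid);
}
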