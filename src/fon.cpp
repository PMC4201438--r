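#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Field-of-neighborhood geometry. Distances in metres, dbh in cm.
// FON radius R = a * r_stem^b with r_stem = dbh/200 (m); never below r_stem.
static inline double fon_R(double dbh, double a, double b) {
  if (dbh <= 0.0) return 0.0;
  double rs = dbh / 200.0;
  double R = a * std::pow(rs, b);
  return (R > rs) ? R : rs;
}

// FON intensity at distance d from the stem axis: 1 on the stem disc,
// exponential decay to lmin at the FON boundary, 0 beyond.
static inline double fon_I(double d, double dbh, double a, double b,
                           double lmin) {
  if (dbh <= 0.0) return 0.0;
  double rs = dbh / 200.0;
  double R = a * std::pow(rs, b);
  if (R < rs) R = rs;
  if (d <= rs) return 1.0;
  if (d > R || R <= rs) return 0.0;
  return std::exp(std::log(lmin) * (d - rs) / (R - rs));
}

// Uniform-grid spatial index so neighbour look-ups stay local.
struct TreeGrid {
  const NumericVector &x, &y, &dbh;
  double x0, y0, cell;
  int nx, ny;
  std::vector<std::vector<int>> cells;

  TreeGrid(const NumericVector &x_, const NumericVector &y_,
           const NumericVector &dbh_, double rmax)
      : x(x_), y(y_), dbh(dbh_) {
    int n = x.size();
    double xmin = 0.0, ymin = 0.0, xmax = 1.0, ymax = 1.0;
    if (n > 0) {
      xmin = *std::min_element(x.begin(), x.end());
      xmax = *std::max_element(x.begin(), x.end());
      ymin = *std::min_element(y.begin(), y.end());
      ymax = *std::max_element(y.begin(), y.end());
    }
    cell = std::max(rmax, 1.0);
    x0 = xmin - cell;
    y0 = ymin - cell;
    nx = (int)std::floor((xmax - x0) / cell) + 2;
    ny = (int)std::floor((ymax - y0) / cell) + 2;
    cells.resize((size_t)nx * ny);
    for (int i = 0; i < n; ++i) {
      int cx = (int)std::floor((x[i] - x0) / cell);
      int cy = (int)std::floor((y[i] - y0) / cell);
      cells[(size_t)cy * nx + cx].push_back(i);
    }
  }

  // Sum of FON intensities of all trees (except `exclude`) at (px, py).
  double field(double px, double py, double a, double b, double lmin,
               int exclude) const {
    int cx = (int)std::floor((px - x0) / cell);
    int cy = (int)std::floor((py - y0) / cell);
    double s = 0.0;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= ny) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= nx) continue;
        const std::vector<int> &bucket = cells[(size_t)yy * nx + xx];
        for (int j : bucket) {
          if (j == exclude) continue;
          double d = std::hypot(px - x[j], py - y[j]);
          s += fon_I(d, dbh[j], a, b, lmin);
        }
      }
    }
    return s;
  }
};

static double max_radius(const NumericVector &dbh, double a, double b) {
  double rmax = 0.0;
  for (double d : dbh) rmax = std::max(rmax, fon_R(d, a, b));
  return rmax;
}

// [[Rcpp::export]]
NumericVector cpp_fon_radius(NumericVector dbh, double fon_a, double fon_b) {
  int n = dbh.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fon_R(dbh[i], fon_a, fon_b);
  return out;
}

// Sum of FON intensities of the stand at arbitrary points; exclude is a
// 1-based tree index (0 = none).
// [[Rcpp::export]]
NumericVector cpp_fon_field(NumericVector px, NumericVector py,
                            NumericVector x, NumericVector y,
                            NumericVector dbh, double fon_a, double fon_b,
                            double fon_min, int exclude = 0) {
  int np = px.size();
  NumericVector out(np);
  if (x.size() == 0) return out;
  TreeGrid grid(x, y, dbh, max_radius(dbh, fon_a, fon_b));
  for (int p = 0; p < np; ++p)
    out[p] = grid.field(px[p], py[p], fon_a, fon_b, fon_min, exclude - 1);
  return out;
}

// Competition index for every tree: mean, over a square quadrature grid
// clipped to the focal FON disc, of the summed neighbour FON intensities.
// Grid spacing is at most `resolution` (the span 2R is divided evenly).
// When `cap` is finite, evaluation stops as soon as the index is provably
// >= cap and returns cap (useful when downstream growth is already zero).
// [[Rcpp::export]]
NumericVector cpp_competition_indices(NumericVector x, NumericVector y,
                                      NumericVector dbh, double fon_a,
                                      double fon_b, double fon_min,
                                      double resolution,
                                      double cap = R_PosInf) {
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  double rmax = max_radius(dbh, fon_a, fon_b);
  TreeGrid grid(x, y, dbh, rmax);

  // scratch space for the focal tree's neighbour list
  std::vector<double> nx_, ny_, nrs, nR, nslope;
  for (int i = 0; i < n; ++i) {
    double R = fon_R(dbh[i], fon_a, fon_b);
    if (R <= 0.0) { out[i] = 0.0; continue; }

    // neighbours whose FON can reach the focal disc
    nx_.clear(); ny_.clear(); nrs.clear(); nR.clear(); nslope.clear();
    double reach = R + rmax;
    int c0x = (int)std::floor((x[i] - reach - grid.x0) / grid.cell);
    int c1x = (int)std::floor((x[i] + reach - grid.x0) / grid.cell);
    int c0y = (int)std::floor((y[i] - reach - grid.y0) / grid.cell);
    int c1y = (int)std::floor((y[i] + reach - grid.y0) / grid.cell);
    c0x = std::max(c0x, 0); c1x = std::min(c1x, grid.nx - 1);
    c0y = std::max(c0y, 0); c1y = std::min(c1y, grid.ny - 1);
    for (int cy = c0y; cy <= c1y; ++cy) {
      for (int cx = c0x; cx <= c1x; ++cx) {
        for (int j : grid.cells[(size_t)cy * grid.nx + cx]) {
          if (j == i || dbh[j] <= 0.0) continue;
          double Rj = fon_R(dbh[j], fon_a, fon_b);
          double d = std::hypot(x[j] - x[i], y[j] - y[i]);
          if (d > R + Rj) continue;
          double rs = dbh[j] / 200.0;
          nx_.push_back(x[j]); ny_.push_back(y[j]);
          nrs.push_back(rs); nR.push_back(Rj);
          nslope.push_back(Rj > rs ? std::log(fon_min) / (Rj - rs) : 0.0);
        }
      }
    }
    if (nx_.empty()) { out[i] = 0.0; continue; }

    int m = (int)std::ceil(2.0 * R / resolution);
    if (m < 1) m = 1;
    double h = 2.0 * R / m;
    double R2 = R * R, acc = 0.0, capacc = cap * (double)m * (double)m;
    long cnt = 0;
    bool capped = false;
    size_t nn = nx_.size();
    for (int k = 0; k < m && !capped; ++k) {
      double px = x[i] - R + (k + 0.5) * h;
      double ddx2 = (px - x[i]) * (px - x[i]);
      for (int l = 0; l < m; ++l) {
        double py = y[i] - R + (l + 0.5) * h;
        double ddy = py - y[i];
        if (ddx2 + ddy * ddy > R2) continue;
        double s = 0.0;
        for (size_t j = 0; j < nn; ++j) {
          double dx = px - nx_[j], dy = py - ny_[j];
          double d2 = dx * dx + dy * dy;
          if (d2 > nR[j] * nR[j]) continue;
          double d = std::sqrt(d2);
          s += (d <= nrs[j]) ? 1.0 : std::exp(nslope[j] * (d - nrs[j]));
        }
        acc += s;
        ++cnt;
        if (acc >= capacc) { capped = true; break; }
      }
    }
    if (capped) {
      out[i] = cap;  // provable lower bound reached
    } else if (cnt > 0) {
      out[i] = acc / cnt;
    } else {
      out[i] = grid.field(x[i], y[i], fon_a, fon_b, fon_min, i);
    }
  }
  return out;
}
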