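#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear surface interpolation on a south-first grid; fractional positions
// clamped to the centre lattice at the margin.  Returns NaN when any
// contributing corner is missing (nodata).
static inline double surf(const NumericMatrix &z, double xll, double yll,
                          double cs, double x, double y) {
  int nr = z.nrow(), nc = z.ncol();
  double fr = (y - yll) / cs - 0.5;
  double fc = (x - xll) / cs - 0.5;
  if (fr < 0) fr = 0; if (fr > nr - 1) fr = nr - 1;
  if (fc < 0) fc = 0; if (fc > nc - 1) fc = nc - 1;
  int r0 = (int)std::floor(fr); if (r0 > nr - 2) r0 = nr - 2; if (r0 < 0) r0 = 0;
  int c0 = (int)std::floor(fc); if (c0 > nc - 2) c0 = nc - 2; if (c0 < 0) c0 = 0;
  int r1 = r0 + 1; if (r1 > nr - 1) r1 = nr - 1;
  int c1 = c0 + 1; if (c1 > nc - 1) c1 = nc - 1;
  double wr = fr - r0, wc = fc - c0;
  double v00 = z(r0, c0), v01 = z(r0, c1), v10 = z(r1, c0), v11 = z(r1, c1);
  return (1.0 - wr) * ((1.0 - wc) * v00 + wc * v01) +
         wr * ((1.0 - wc) * v10 + wc * v11);
}

// One sight line: observer eye at (ox, oy, oz) to the centre of cell
// (r, c) (0-based, row 0 = south) at its stored surface elevation.  The
// surface is sampled every los_step strictly between the endpoints; a sample
// blocks when it lies strictly above the straight sight line.  Nodata
// samples block nothing; a nodata target is never visible; the observer's
// own cell is always visible.
static bool los(const NumericMatrix &z, double xll, double yll, double cs,
                double ox, double oy, double oz, int r, int c,
                double los_step) {
  double tz = z(r, c);
  if (ISNAN(tz)) return false;
  double tx = xll + (c + 0.5) * cs;
  double ty = yll + (r + 0.5) * cs;
  int orow = (int)std::floor((oy - yll) / cs);
  int ocol = (int)std::floor((ox - xll) / cs);
  if (orow == r && ocol == c) return true;
  double d = std::sqrt((tx - ox) * (tx - ox) + (ty - oy) * (ty - oy));
  if (d <= 0) return true;
  for (int k = 1; k * los_step < d - 1e-9; ++k) {
    double t = k * los_step / d;
    double sx = ox + (tx - ox) * t;
    double sy = oy + (ty - oy) * t;
    double sz = surf(z, xll, yll, cs, sx, sy);
    if (ISNAN(sz)) continue;
    double lz = oz + (tz - oz) * t;
    if (sz > lz) return false;
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_line_of_sight(NumericMatrix z, double xll, double yll,
                                double cs, NumericVector ox, NumericVector oy,
                                NumericVector oz, IntegerVector row0,
                                IntegerVector col0, double los_step) {
  int n = row0.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    int oi = ox.size() == 1 ? 0 : i;
    out[i] = los(z, xll, yll, cs, ox[oi], oy[oi], oz[oi],
                 row0[i], col0[i], los_step);
  }
  return out;
}

// Cumulative viewshed counts for an explicit list of target cells (0-based
// row/col, row 0 = south).  A cell's count is the number of observers whose
// horizontal distance to the cell centre is at most max_distance and whose
// sight line to the cell is unobstructed.
// [[Rcpp::export]]
IntegerVector cpp_viewshed_counts(NumericMatrix z, double xll, double yll,
                                  double cs, NumericMatrix obs,
                                  IntegerVector row0, IntegerVector col0,
                                  double max_distance, double los_step) {
  int n = row0.size(), m = obs.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int r = row0[i], c = col0[i];
    if (ISNAN(z(r, c))) { out[i] = 0; continue; }
    double tx = xll + (c + 0.5) * cs;
    double ty = yll + (r + 0.5) * cs;
    int cnt = 0;
    for (int j = 0; j < m; ++j) {
      double dx = tx - obs(j, 0), dy = ty - obs(j, 1);
      if (dx * dx + dy * dy > max_distance * max_distance) continue;
      if (los(z, xll, yll, cs, obs(j, 0), obs(j, 1), obs(j, 2), r, c,
              los_step))
        ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}
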