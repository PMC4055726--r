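#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Even-odd membership of one point in a collection of rings, with an
// optional boundary test (points within 1e-9 m of a ring edge count as
// inside).  Shared by the exported point and segment-clipping routines.
static bool pt_in_rings(double x, double y,
                        const std::vector<NumericMatrix> &rings,
                        bool boundary) {
  bool inside = false, on = false;
  const double eps2 = 1e-18;
  for (size_t k = 0; k < rings.size(); ++k) {
    const NumericMatrix &m = rings[k];
    int n = m.nrow();
    for (int i = 0, j = n - 1; i < n; j = i++) {
      double xi = m(i, 0), yi = m(i, 1), xj = m(j, 0), yj = m(j, 1);
      if (((yi > y) != (yj > y)) &&
          (x < (xj - xi) * (y - yi) / (yj - yi) + xi))
        inside = !inside;
      if (boundary && !on) {
        double dx = xj - xi, dy = yj - yi;
        double len2 = dx * dx + dy * dy;
        double t = len2 > 0 ? ((x - xi) * dx + (y - yi) * dy) / len2 : 0.0;
        if (t < 0) t = 0; if (t > 1) t = 1;
        double ddx = x - (xi + t * dx), ddy = y - (yi + t * dy);
        if (ddx * ddx + ddy * ddy < eps2) on = true;
      }
    }
  }
  return inside || on;
}

static std::vector<NumericMatrix> ring_vec(List rings) {
  std::vector<NumericMatrix> out;
  for (int i = 0; i < rings.size(); ++i)
    out.push_back(as<NumericMatrix>(rings[i]));
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_rings(NumericVector px, NumericVector py,
                                  List rings, bool boundary) {
  std::vector<NumericMatrix> R = ring_vec(rings);
  int np = px.size();
  LogicalVector out(np);
  for (int p = 0; p < np; ++p)
    out[p] = pt_in_rings(px[p], py[p], R, boundary);
  return out;
}

// Total length of the segment portions lying inside the ring region
// (even-odd): each segment is cut at every ring-edge crossing and the
// sub-intervals whose midpoints fall inside are summed.
// [[Rcpp::export]]
double cpp_clip_length(NumericMatrix segs, List rings) {
  std::vector<NumericMatrix> R = ring_vec(rings);
  double total = 0.0;
  std::vector<double> ts;
  for (int s = 0; s < segs.nrow(); ++s) {
    double x1 = segs(s, 0), y1 = segs(s, 1), x2 = segs(s, 2), y2 = segs(s, 3);
    ts.clear();
    ts.push_back(0.0); ts.push_back(1.0);
    for (size_t k = 0; k < R.size(); ++k) {
      const NumericMatrix &m = R[k];
      int n = m.nrow();
      for (int i = 0, j = n - 1; i < n; j = i++) {
        double x3 = m(j, 0), y3 = m(j, 1), x4 = m(i, 0), y4 = m(i, 1);
        double denom = (x2 - x1) * (y4 - y3) - (y2 - y1) * (x4 - x3);
        if (std::fabs(denom) < 1e-12) continue;
        double t = ((x3 - x1) * (y4 - y3) - (y3 - y1) * (x4 - x3)) / denom;
        double u = ((x3 - x1) * (y2 - y1) - (y3 - y1) * (x2 - x1)) / denom;
        if (t >= 0 && t <= 1 && u >= 0 && u <= 1) ts.push_back(t);
      }
    }
    std::sort(ts.begin(), ts.end());
    double seglen = std::sqrt((x2 - x1) * (x2 - x1) + (y2 - y1) * (y2 - y1));
    for (size_t i = 0; i + 1 < ts.size(); ++i) {
      double dt = ts[i + 1] - ts[i];
      if (dt <= 0) continue;
      double tm = (ts[i] + ts[i + 1]) / 2;
      if (pt_in_rings(x1 + tm * (x2 - x1), y1 + tm * (y2 - y1), R, false))
        total += dt * seglen;
    }
  }
  return total;
}
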