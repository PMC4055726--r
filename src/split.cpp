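#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gini impurity decrease of a candidate split on the count scale:
// n*g(parent) - nL*g(L) - nR*g(R).
static inline double gain_of(int n, int n1, int nL, int n1L,
                             double parent_cost) {
  int n0 = n - n1;
  int n0L = nL - n1L;
  int nR = n - nL, n1R = n1 - n1L, n0R = n0 - n0L;
  double costL = nL - ((double)n0L * n0L + (double)n1L * n1L) / nL;
  double costR = nR - ((double)n0R * n0R + (double)n1R * n1R) / nR;
  return parent_cost - costL - costR;
}

// Exhaustive best-split search at one node.  Candidates are canonically
// ordered (declared variable order; ascending numeric thresholds;
// categorical left-subset bit patterns over the first m-1 observed levels);
// the returned split is the first candidate whose gain is within eps of the
// maximum.  Two passes: max gain, then first qualifying candidate.
//
// cols: list of numeric vectors or integer factor codes (1-based);
// is_cat marks factor columns.  Returns R_NilValue when no candidate gains
// more than eps.
// [[Rcpp::export]]
SEXP cpp_best_split(List cols, LogicalVector is_cat, IntegerVector y,
                    int min_leaf, double eps) {
  int p = cols.size();
  int n = y.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[i];
  double parent_cost =
      n - ((double)(n - n1) * (n - n1) + (double)n1 * n1) / n;

  double max_gain = 0.0;
  for (int pass = 0; pass < 2; ++pass) {
    for (int j = 0; j < p; ++j) {
      if (is_cat[j]) {
        IntegerVector xv = cols[j];
        int maxlev = 0;
        for (int i = 0; i < n; ++i) maxlev = std::max(maxlev, xv[i]);
        std::vector<int> cnt(maxlev + 1, 0), cnt1(maxlev + 1, 0);
        for (int i = 0; i < n; ++i) { cnt[xv[i]]++; cnt1[xv[i]] += y[i]; }
        std::vector<int> obs;
        for (int l = 1; l <= maxlev; ++l) if (cnt[l] > 0) obs.push_back(l);
        int m = obs.size();
        if (m < 2) continue;
        int nsub = (1 << (m - 1)) - 1;
        for (int bits = 1; bits <= nsub; ++bits) {
          int nL = 0, n1L = 0;
          for (int b = 0; b < m - 1; ++b)
            if (bits & (1 << b)) { nL += cnt[obs[b]]; n1L += cnt1[obs[b]]; }
          if (nL < min_leaf || n - nL < min_leaf) continue;
          double g = gain_of(n, n1, nL, n1L, parent_cost);
          if (pass == 0) {
            if (g > max_gain) max_gain = g;
          } else if (g >= max_gain - eps) {
            IntegerVector left;
            for (int b = 0; b < m - 1; ++b)
              if (bits & (1 << b)) left.push_back(obs[b]);
            IntegerVector right;
            for (int b = 0; b < m; ++b) {
              bool inl = b < m - 1 && (bits & (1 << b));
              if (!inl) right.push_back(obs[b]);
            }
            return List::create(_["var"] = j + 1, _["kind"] = "categorical",
                                _["left_codes"] = left,
                                _["right_codes"] = right,
                                _["improvement"] = g);
          }
        }
      } else {
        NumericVector xv = cols[j];
        std::vector<int> ord(n);
        for (int i = 0; i < n; ++i) ord[i] = i;
        std::stable_sort(ord.begin(), ord.end(),
                         [&](int a, int b) { return xv[a] < xv[b]; });
        int cum1 = 0;
        for (int i = 0; i < n - 1; ++i) {
          cum1 += y[ord[i]];
          int nL = i + 1;
          if (xv[ord[i]] >= xv[ord[i + 1]]) continue;
          if (nL < min_leaf || n - nL < min_leaf) continue;
          double g = gain_of(n, n1, nL, cum1, parent_cost);
          if (pass == 0) {
            if (g > max_gain) max_gain = g;
          } else if (g >= max_gain - eps) {
            return List::create(
                _["var"] = j + 1, _["kind"] = "numeric",
                _["threshold"] = (xv[ord[i]] + xv[ord[i + 1]]) / 2,
                _["improvement"] = g);
          }
        }
      }
    }
    if (pass == 0 && max_gain <= eps) return R_NilValue;
  }
  return R_NilValue;
}
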