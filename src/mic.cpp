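// Exact maximal information coefficient by exhaustive grid search.
//
// MIC(x, y) = max over axis-aligned grids (k x l cells, k*l <= B) of
// I(X_binned; Y_binned) / log2(min(k, l)), where bin boundaries are cuts
// between consecutive points in each variable's sort order. The search is
// exhaustive over all cut placements, which is feasible because the grid
// bound B = n^b keeps k and l tiny at the sample sizes this package
// targets (n <= ~40); the value is exact and deterministic.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// enumerate all ways to choose (k-1) cut positions among n-1 gaps
struct CutIter {
  int n, k;
  std::vector<int> cuts; // cut after position cuts[i] (1-based, ascending)
  bool first;
  CutIter(int n_, int k_) : n(n_), k(k_), cuts(k_ - 1), first(true) {
    for (int i = 0; i < k - 1; ++i) cuts[i] = i + 1;
  }
  bool next() {
    if (first) { first = false; return true; }
    int m = k - 1;
    for (int i = m - 1; i >= 0; --i) {
      if (cuts[i] < n - 1 - (m - 1 - i)) {
        ++cuts[i];
        for (int j = i + 1; j < m; ++j) cuts[j] = cuts[j - 1] + 1;
        return true;
      }
    }
    return false;
  }
};

// assign each point (by sort position) to its bin given cuts
inline void assignBins(const std::vector<int>& order,
                       const std::vector<int>& cuts,
                       std::vector<int>& bin) {
  int b = 0;
  int m = (int)cuts.size();
  for (size_t p = 0; p < order.size(); ++p) {
    while (b < m && (int)p >= cuts[b]) ++b;
    bin[order[p]] = b;
  }
}

double mutualInfo(const std::vector<int>& xb, const std::vector<int>& yb,
                  int k, int l, std::vector<double>& joint) {
  int n = (int)xb.size();
  std::fill(joint.begin(), joint.end(), 0.0);
  std::vector<double> px(k, 0.0), py(l, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[xb[i] * l + yb[i]] += 1.0;
    px[xb[i]] += 1.0;
    py[yb[i]] += 1.0;
  }
  double mi = 0.0, dn = (double)n;
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < l; ++b) {
      double c = joint[a * l + b];
      if (c > 0.0)
        mi += (c / dn) * std::log2(c * dn / (px[a] * py[b]));
    }
  return mi;
}

} // namespace

// order of indices by (value, index); deterministic under ties
static std::vector<int> sortOrder(const NumericVector& v) {
  int n = v.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// [[Rcpp::export(name = ".micExhaustive")]]
double micExhaustive(NumericVector x, NumericVector y, double B,
                     double max_evals = 5e7) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 4) stop("MIC needs n >= 4");
  std::vector<int> xo = sortOrder(x), yo = sortOrder(y);

  double best = 0.0;
  int maxb = (int)std::floor(B / 2.0);
  // total work guard
  double total = 0.0;
  for (int k = 2; k <= maxb; ++k)
    for (int l = 2; (double)k * l <= B; ++l) {
      double ck = 1.0, cl = 1.0; // C(n-1, k-1), C(n-1, l-1)
      for (int i = 1; i < k; ++i) ck = ck * (n - i) / i;
      for (int i = 1; i < l; ++i) cl = cl * (n - i) / i;
      total += ck * cl * n;
    }
  if (total > max_evals)
    stop("exact MIC search too large at n = %d (work ~%.2e); "
         "reduce n or the grid bound", n, total);

  std::vector<int> xb(n), yb(n);
  for (int k = 2; k <= maxb; ++k) {
    for (int l = 2; (double)k * l <= B; ++l) {
      double norm = std::log2((double)std::min(k, l));
      std::vector<double> joint((size_t)k * l);
      CutIter xc(n, k);
      while (xc.next()) {
        assignBins(xo, xc.cuts, xb);
        CutIter yc(n, l);
        while (yc.next()) {
          assignBins(yo, yc.cuts, yb);
          double v = mutualInfo(xb, yb, k, l, joint) / norm;
          if (v > best) best = v;
        }
      }
    }
  }
  if (best > 1.0) best = 1.0; // clamp rounding noise
  return best;
}
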