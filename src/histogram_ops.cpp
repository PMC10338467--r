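#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scatter each nonzero bin's weight uniformly over a boxcar window of
// per-bin half-width (in bins), via a difference array. Window mass falling
// outside [1, nbins] is absorbed by the corresponding edge bin, so the total
// weight is conserved exactly.
//
// idx: 1-based bin indices of nonzero bins; val: their weights;
// halfwidth: per-bin window half-width in bins (>= 0).
// [[Rcpp::export]]
NumericVector boxcar_scatter(int nbins, IntegerVector idx, NumericVector val,
                             IntegerVector halfwidth) {
  std::vector<double> d(nbins + 1, 0.0);
  double edge_lo = 0.0, edge_hi = 0.0;
  R_xlen_t m = idx.size();
  for (R_xlen_t t = 0; t < m; ++t) {
    int i = idx[t];
    int k = halfwidth[t];
    double v = val[t] / (2.0 * k + 1.0);
    int lo = i - k, hi = i + k;
    if (lo < 1) { edge_lo += (1 - lo) * v; lo = 1; }
    if (hi > nbins) { edge_hi += (hi - nbins) * v; hi = nbins; }
    d[lo - 1] += v;
    d[hi] -= v;
  }
  NumericVector out(nbins);
  double acc = 0.0;
  for (int b = 0; b < nbins; ++b) {
    acc += d[b];
    out[b] = acc;
  }
  if (nbins > 0) {
    out[0] += edge_lo;
    out[nbins - 1] += edge_hi;
  }
  return out;
}

// Apex detection by peak descent. Local maxima (w[i] > 0, no smaller than
// either neighbour; runs of equal bins count once, at the run centre) are
// visited in decreasing height order; from each unclaimed maximum both
// sides are descended, tolerating bin-to-bin increases of up to descent_tol
// (relative), until a zero bin or a larger increase ends the walk. Bins
// traversed are claimed; maxima inside a claimed region are shoulders of a
// larger peak and are not reported.
// Returns 1-based apex bin indices in ascending order.
// [[Rcpp::export]]
IntegerVector descend_apexes(NumericVector w, double descent_tol) {
  int n = w.size();
  std::vector<int> cand;
  int i = 0;
  while (i < n) {
    if (w[i] <= 0) { ++i; continue; }
    int j = i;  // run of equal values [i, j]
    while (j + 1 < n && w[j + 1] == w[i]) ++j;
    double l = (i > 0) ? w[i - 1] : 0.0;
    double r = (j < n - 1) ? w[j + 1] : 0.0;
    if (w[i] >= l && w[i] >= r) cand.push_back((i + j) / 2);
    i = j + 1;
  }
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (w[a] != w[b]) return w[a] > w[b];
    return a < b;
  });
  std::vector<char> claimed(n, 0);
  std::vector<int> apex;
  for (size_t c = 0; c < cand.size(); ++c) {
    int i = cand[c];
    if (claimed[i]) continue;
    apex.push_back(i + 1);
    claimed[i] = 1;
    int j = i;
    while (j > 0 && w[j - 1] > 0 && w[j - 1] <= w[j] * (1.0 + descent_tol)) {
      --j;
      claimed[j] = 1;
    }
    j = i;
    while (j < n - 1 && w[j + 1] > 0 && w[j + 1] <= w[j] * (1.0 + descent_tol)) {
      ++j;
      claimed[j] = 1;
    }
  }
  std::sort(apex.begin(), apex.end());
  return wrap(apex);
}
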