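#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Linear-interpolation quantile (R type 7) of a sorted vector.
static double sorted_quantile(const std::vector<double>& s, double p) {
  const int n = s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

// Running percentile over a centered window of `window` frames, truncated at
// the edges. Maintains a sorted buffer with binary-search insert/erase.
// [[Rcpp::export]]
NumericVector running_percentile(NumericVector x, int window, double p) {
  const int n = x.size();
  NumericVector out(n);
  const int half = window / 2;
  int lo = 0, hi = std::min(n, half + 1); // window [lo, hi) for frame 0
  std::vector<double> buf(x.begin() + lo, x.begin() + hi);
  std::sort(buf.begin(), buf.end());
  for (int i = 0; i < n; ++i) {
    int nlo = std::max(0, i - half);
    int nhi = std::min(n, i + half + 1);
    while (hi < nhi) {
      buf.insert(std::upper_bound(buf.begin(), buf.end(), x[hi]), x[hi]);
      ++hi;
    }
    while (lo < nlo) {
      buf.erase(std::lower_bound(buf.begin(), buf.end(), x[lo]));
      ++lo;
    }
    out[i] = sorted_quantile(buf, p);
  }
  return out;
}
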