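#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Quantile of an already-sorted window, matching R's default (type 7):
// linear interpolation between order statistics at position p*(m-1).
static double sorted_quantile(const std::vector<double>& w, double p) {
  const int m = (int)w.size();
  if (m == 1) return w[0];
  double pos = p * (m - 1);
  int lo = (int)std::floor(pos);
  if (lo + 1 >= m) return w[m - 1];
  double frac = pos - lo;
  return w[lo] + frac * (w[lo + 1] - w[lo]);
}

// Rolling quantile over a centred window [i - halfwidth, i + halfwidth],
// truncated at the trace edges.  The window is kept as a sorted vector and
// updated incrementally (binary search + memmove), which is far cheaper than
// re-sorting per frame for the 150 s windows used for baseline estimation.
// [[Rcpp::export(rng = false)]]
NumericVector roll_quantile_cpp(NumericVector x, int halfwidth, double p) {
  const int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> win;
  win.reserve(2 * (size_t)halfwidth + 2);
  const int hi0 = std::min(halfwidth, n - 1);
  for (int j = 0; j <= hi0; ++j) win.push_back(x[j]);
  std::sort(win.begin(), win.end());
  for (int i = 0; i < n; ++i) {
    out[i] = sorted_quantile(win, p);
    const int add = i + 1 + halfwidth;   // entering the window centred at i+1
    if (add < n) {
      const double v = x[add];
      win.insert(std::upper_bound(win.begin(), win.end(), v), v);
    }
    const int drop = i - halfwidth;      // leaving the window centred at i+1
    if (drop >= 0) {
      const double v = x[drop];
      win.erase(std::lower_bound(win.begin(), win.end(), v));
    }
  }
  return out;
}
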