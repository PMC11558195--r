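#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// median of v, destroying the order of v
static double median_inplace(std::vector<double>& v) {
  const size_t n = v.size();
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  double lo = *std::max_element(v.begin(), v.begin() + n / 2);
  return 0.5 * (lo + hi);
}

// Windowed median and MAD for the Hampel identifier.
// Windows are centered (half points each side), truncated at the series
// edges, and restricted to valid entries; centers that are invalid or have
// fewer than min_count valid points in their window get NA.
// [[Rcpp::export]]
List hampel_window_stats(NumericVector x, LogicalVector valid, int half,
                         int min_count) {
  const int n = x.size();
  NumericVector med(n, NA_REAL), mad(n, NA_REAL);
  std::vector<double> w;
  w.reserve(2 * half + 1);
  for (int i = 0; i < n; ++i) {
    if (valid[i] != TRUE) continue;
    const int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    w.clear();
    for (int j = lo; j <= hi; ++j)
      if (valid[j] == TRUE) w.push_back(x[j]);
    if (static_cast<int>(w.size()) < min_count) continue;
    const double m = median_inplace(w);
    for (size_t k = 0; k < w.size(); ++k) w[k] = std::fabs(w[k] - m);
    med[i] = m;
    mad[i] = median_inplace(w);
  }
  return List::create(_["median"] = med, _["mad"] = mad);
}
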