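#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Rolling Welch t-statistic event segmentation.  For each window length w,
// t[i] compares samples [i-w, i) against [i, i+w); boundaries are placed at
// local maxima exceeding the detector's threshold, and an accepted peak
// suppresses further boundaries from the same detector for w samples.
// [[Rcpp::export]]
IntegerVector detect_boundaries_cpp(NumericVector x, IntegerVector windows,
                                    NumericVector thresholds) {
  const int n = x.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  std::vector<int> bounds;
  for (int d = 0; d < windows.size(); ++d) {
    const int w = windows[d];
    const double thr = thresholds[d];
    if (2 * w > n) continue;
    std::vector<double> t(n, 0.0);
    for (int i = w; i + w <= n; ++i) {
      double m1 = (cs[i] - cs[i - w]) / w;
      double m2 = (cs[i + w] - cs[i]) / w;
      double v1 = (cs2[i] - cs2[i - w]) / w - m1 * m1;
      double v2 = (cs2[i + w] - cs2[i]) / w - m2 * m2;
      if (v1 < 0) v1 = 0;
      if (v2 < 0) v2 = 0;
      double den = std::sqrt(v1 / w + v2 / w);
      if (den < 1e-10) den = 1e-10;
      t[i] = std::fabs(m1 - m2) / den;
    }
    int last = -w - 1;
    for (int i = w; i + w <= n; ++i) {
      if (t[i] < thr) continue;
      double prev = (i > 0) ? t[i - 1] : 0.0;
      double next = (i + 1 < n) ? t[i + 1] : 0.0;
      if (t[i] >= prev && t[i] > next && i - last > w) {
        bounds.push_back(i);
        last = i;
      }
    }
  }
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  return wrap(bounds);
}
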