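#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Banded DTW between event means (rows i) and expected reference means
// (columns j).  The band gives, per column j, the allowed event-index
// interval [top[j], bottom[j]) in 0-based coordinates.  Recurrence with a
// multiplicative penalty on the skip step's cost term:
//   D[i,j] = min(cost + D[i-1,j-1], cost + D[i-1,j],
//                skip * cost + D[i,j-1])
// with D[0,0] = cost(0,0) and cells outside the band infinite.
// cost(i,j) = |event[i] - expected[j]| (optionally z-scaled by exp_sd).
// Tie-break: diagonal > stay (from i-1,j) > skip (from i,j-1).
// [[Rcpp::export]]
List banded_dtw_cpp(NumericVector event_means, NumericVector exp_means,
                    NumericVector exp_sds, IntegerVector top,
                    IntegerVector bottom, double skip_cost, bool z_cost) {
  const int N = event_means.size();
  const int M = exp_means.size();
  const double INF = std::numeric_limits<double>::infinity();
  if (M == 0 || N == 0) stop("empty inputs to banded DTW");
  if (top.size() != M || bottom.size() != M) stop("band length != reference length");

  // column offsets into the flattened band storage
  std::vector<int> off(M + 1, 0);
  for (int j = 0; j < M; ++j) {
    if (bottom[j] <= top[j] || top[j] < 0 || bottom[j] > N)
      stop("invalid band at column %d", j + 1);
    off[j + 1] = off[j] + (bottom[j] - top[j]);
  }
  std::vector<double> D(off[M], INF);
  std::vector<signed char> mv(off[M], -1); // 0 diag, 1 stay, 2 skip, 3 origin

  auto cell = [&](int i, int j) -> double {
    if (j < 0 || i < 0) return INF;
    if (i < top[j] || i >= bottom[j]) return INF;
    return D[off[j] + (i - top[j])];
  };
  auto cost = [&](int i, int j) -> double {
    double c = std::fabs(event_means[i] - exp_means[j]);
    if (z_cost) c /= exp_sds[j];
    return c;
  };

  for (int j = 0; j < M; ++j) {
    for (int i = top[j]; i < bottom[j]; ++i) {
      double c = cost(i, j);
      int idx = off[j] + (i - top[j]);
      if (i == 0 && j == 0) { D[idx] = c; mv[idx] = 3; continue; }
      double t_diag = c + cell(i - 1, j - 1);
      double t_stay = c + cell(i - 1, j);
      double t_skip = skip_cost * c + cell(i, j - 1);
      double best = t_diag; signed char m = 0;
      if (t_stay < best) { best = t_stay; m = 1; }
      if (t_skip < best) { best = t_skip; m = 2; }
      if (!std::isfinite(best)) continue; // unreachable cell stays infinite
      D[idx] = best;
      mv[idx] = m;
    }
  }

  double total = cell(N - 1, M - 1);
  if (!std::isfinite(total))
    return List::create(_["cost"] = R_PosInf);

  // traceback
  std::vector<int> pi, pj; std::vector<int> pmove;
  int i = N - 1, j = M - 1;
  while (true) {
    int idx = off[j] + (i - top[j]);
    pi.push_back(i); pj.push_back(j); pmove.push_back(mv[idx]);
    if (mv[idx] == 3) break;
    if (mv[idx] == 0) { --i; --j; }
    else if (mv[idx] == 1) { --i; }
    else { --j; }
  }
  const int L = pi.size();
  IntegerVector out_i(L), out_j(L), out_m(L);
  for (int t = 0; t < L; ++t) {
    out_i[t] = pi[L - 1 - t];
    out_j[t] = pj[L - 1 - t];
    out_m[t] = pmove[L - 1 - t];
  }
  return List::create(_["cost"] = total, _["event"] = out_i,
                      _["ref"] = out_j, _["move"] = out_m);
}
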