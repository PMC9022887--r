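#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact two-sided permutation p-value for Spearman's rho by full enumeration.
//
// xr, yr: rank vectors (average ranks for ties). Enumerates every distinct
// arrangement of yr with std::next_permutation; under the permutation null
// all distinct arrangements of a (possibly tied) rank vector are equally
// likely, so the distinct-arrangement average is the exact law.
// Two-sided: P(|rho_perm| >= |rho_obs|), which only needs the cross moment
// sum(xr * yr) since the marginal moments are permutation-invariant.
// Feasible for n <= 10 (10! = 3.6e6 arrangements).
// [[Rcpp::export]]
double cpp_spearman_exact_p(NumericVector xr, NumericVector yr) {
  const int n = xr.size();
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += xr[i]; my += yr[i]; }
  mx /= n; my /= n;

  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += xr[i] * yr[i];
  const double obs_dev = std::fabs(obs - n * mx * my);

  std::vector<double> y(yr.begin(), yr.end());
  std::sort(y.begin(), y.end());

  long long total = 0, ge = 0;
  const double eps = 1e-9;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xr[i] * y[i];
    if (std::fabs(s - n * mx * my) >= obs_dev - eps) ++ge;
    ++total;
  } while (std::next_permutation(y.begin(), y.end()));

  return static_cast<double>(ge) / static_cast<double>(total);
}
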