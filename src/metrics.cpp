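#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic-time-warping alignment cost between two ascending position
// sequences under the pointwise distance |r - s|. Boundary D(0,0) = 0,
// other border cells infinite; recursion
//   D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1)).
// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector a, NumericVector b) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("dtw_cost: empty sequence");
  std::vector<double> prev(n + 1, R_PosInf), cur(n + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= m; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= n; ++j) {
      double best = std::min(prev[j], std::min(cur[j - 1], prev[j - 1]));
      cur[j] = std::fabs(a[i - 1] - b[j - 1]) + best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Sliding-window hydropathy dissimilarity: the shorter profile `a`
// traverses the longer profile `b` at stride `step`; at each offset the
// weighted Lp mean of absolute hydropathy differences is taken, and the
// minimum over offsets t = 0..floor((n - m)/step) is returned.
// `w` has one weight per position of `a`; `W` is the normalising total
// weight (the length of the shorter chain by default).
// [[Rcpp::export]]
double hydro_min_cost_cpp(NumericVector a, NumericVector b, int step,
                          NumericVector w, double p, double W) {
  const int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("hydro distance: empty profile");
  if (m > n) stop("hydro distance: first profile must be the shorter");
  const int tmax = (n - m) / step;
  double best = R_PosInf;
  for (int t = 0; t <= tmax; ++t) {
    const int off = step * t;
    double s = 0.0;
    for (int k = 0; k < m; ++k) {
      double d = std::fabs(a[k] - b[off + k]);
      s += w[k] * (p == 1.0 ? d : std::pow(d, p));
    }
    s /= W;
    double val = (p == 1.0) ? s : std::pow(s, 1.0 / p);
    if (val < best) best = val;
  }
  return best;
}
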