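#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Classic dynamic time warping with Euclidean local cost and the symmetric
// (match/insert/delete) step pattern; full DP table, no window constraint.
// [[Rcpp::export]]
double cpp_dtw(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow(), d = a.ncol();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i - 1, k) - b(j - 1, k);
        c += diff * diff;
      }
      c = std::sqrt(c);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
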