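#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic-programming DTW with unit steps (match/insert/delete),
// local cost |a_i - b_j|, no window constraint. Two rolling rows keep the
// memory at O(m); raw pointers keep the inner loop tight.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: empty sequence");
  std::vector<double> row1(m + 1, R_PosInf), row2(m + 1, R_PosInf);
  double *prev = row1.data(), *cur = row2.data();
  const double *pa = a.begin(), *pb = b.begin();
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    const double ai = pa[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double c = std::fabs(ai - pb[j - 1]);
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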