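#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch with linear gap penalty and free end gaps, maximizing the
// summed cell scores. Deterministic tie-break: diagonal > up (gap in b) >
// left (gap in a). Returns the aligned index pairs (1-based), one row per
// matched (i, j).
// [[Rcpp::export(name = ".nw_align_c")]]
IntegerMatrix nw_align_c(NumericMatrix S, double gap) {
  int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix ptr(n + 1, m + 1);  // 0 stop, 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) { F(i, 0) = 0; ptr(i, 0) = 2; }
  for (int j = 1; j <= m; ++j) { F(0, j) = 0; ptr(0, j) = 3; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double gi = (j == m) ? 0.0 : gap;  // free end gaps
      double gj = (i == n) ? 0.0 : gap;
      double up = F(i - 1, j) - gi;
      double left = F(i, j - 1) - gj;
      if (diag >= up && diag >= left) { F(i, j) = diag; ptr(i, j) = 1; }
      else if (up >= left) { F(i, j) = up; ptr(i, j) = 2; }
      else { F(i, j) = left; ptr(i, j) = 3; }
    }
  }
  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = ptr(i, j);
    if (p == 1) { ai.push_back(i); bj.push_back(j); --i; --j; }
    else if (p == 2) { --i; }
    else if (p == 3) { --j; }
    else break;
  }
  int k = ai.size();
  IntegerMatrix out(k, 2);
  for (int t = 0; t < k; ++t) {
    out(t, 0) = ai[k - 1 - t];
    out(t, 1) = bj[k - 1 - t];
  }
  return out;
}
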