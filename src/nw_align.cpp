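#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment over an arbitrary similarity matrix
// with a linear gap penalty. Returns the 1-based aligned index pairs,
// strictly increasing in both columns. Ties prefer diagonal, then up.
// [[Rcpp::export]]
IntegerMatrix nw_align_cpp(NumericMatrix S, double gap) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix F(n + 1, m + 1);
  IntegerMatrix ptr(n + 1, m + 1); // 0 = diag, 1 = up, 2 = left
  for (int i = 1; i <= n; ++i) { F(i, 0) = F(i - 1, 0) + gap; ptr(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { F(0, j) = F(0, j - 1) + gap; ptr(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + S(i - 1, j - 1);
      double up = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      if (diag >= up && diag >= left) { F(i, j) = diag; ptr(i, j) = 0; }
      else if (up >= left)            { F(i, j) = up;   ptr(i, j) = 1; }
      else                            { F(i, j) = left; ptr(i, j) = 2; }
    }
  }
  std::vector<int> ai, bj;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int p = ptr(i, j);
    if (i > 0 && j > 0 && p == 0) { ai.push_back(i); bj.push_back(j); --i; --j; }
    else if (i > 0 && (p == 1 || j == 0)) { --i; }
    else { --j; }
  }
  const int k = (int)ai.size();
  IntegerMatrix out(k, 2);
  for (int q = 0; q < k; ++q) {
    out(q, 0) = ai[k - 1 - q];
    out(q, 1) = bj[k - 1 - q];
  }
  return out;
}
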