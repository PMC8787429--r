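#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Constrained dynamic time warping with step set {(1,0),(0,1),(1,1)},
// squared-difference local cost and a Sakoe-Chiba band |i - j| <= band
// (0-based indices). Ties are broken by preferring the diagonal step,
// then the query-advancing (1,0) step. Returns the cumulative cost
// (including the local cost at (0,0)) and the optimal path, 1-based.
// [[Rcpp::export]]
List dtw_core(NumericVector x, NumericVector y, int band) {
  const int m = x.size(), n = y.size();
  const double INF = R_PosInf;
  std::vector<double> D((size_t)m * n, INF);
  std::vector<signed char> st((size_t)m * n, -1); // 0 diag, 1 (1,0), 2 (0,1)
  auto id = [n](int i, int j) { return (size_t)i * n + j; };

  for (int i = 0; i < m; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(n - 1, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      double d = x[i] - y[j];
      d *= d;
      if (i == 0 && j == 0) {
        D[id(0, 0)] = d;
        continue;
      }
      double cd = (i > 0 && j > 0) ? D[id(i - 1, j - 1)] : INF;
      double cu = (i > 0) ? D[id(i - 1, j)] : INF;
      double cl = (j > 0) ? D[id(i, j - 1)] : INF;
      double best = std::min(cd, std::min(cu, cl));
      if (best == INF) continue;
      D[id(i, j)] = d + best;
      st[id(i, j)] = (cd == best) ? 0 : ((cu == best) ? 1 : 2);
    }
  }

  double cost = D[id(m - 1, n - 1)];
  if (!R_FINITE(cost)) {
    return List::create(_["cost"] = cost,
                        _["path"] = IntegerMatrix(0, 2));
  }
  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i + 1);
  pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    signed char s = st[id(i, j)];
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
    pi.push_back(i + 1);
    pj.push_back(j + 1);
  }
  const int len = pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {
    path(k, 0) = pi[len - 1 - k];
    path(k, 1) = pj[len - 1 - k];
  }
  colnames(path) = CharacterVector::create("query", "template");
  return List::create(_["cost"] = cost, _["path"] = path);
}
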