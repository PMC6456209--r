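// Global affine-gap alignment (Gotoh) over a precomputed column-score
// matrix.  Works for single sequences (scores looked up from a
// substitution matrix) and for profiles (scores = f_a' S f_b), so the
// same kernel drives pairwise and progressive alignment.
//
// Gap cost: a run of L gap columns costs gap_open + (L-1)*gap_extend
// (both negative).  Deterministic traceback preference:
// match/mismatch > gap in the first sequence > gap in the second.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export]]
List c_affine_align(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  // M: a_i ~ b_j ; X: gap in second seq (consumes a_i) ; Y: gap in first
  std::vector<double> M((n + 1) * (m + 1), NEG), X = M, Y = M;
  auto id = [m](int i, int j) { return i * (m + 1) + j; };
  M[id(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[id(i, 0)] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j)
    Y[id(0, j)] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double p = std::max(M[id(i - 1, j - 1)],
                          std::max(X[id(i - 1, j - 1)], Y[id(i - 1, j - 1)]));
      M[id(i, j)] = p + S(i - 1, j - 1);
      X[id(i, j)] = std::max(std::max(M[id(i - 1, j)], Y[id(i - 1, j)]) + gap_open,
                             X[id(i - 1, j)] + gap_extend);
      Y[id(i, j)] = std::max(std::max(M[id(i, j - 1)], X[id(i, j - 1)]) + gap_open,
                             Y[id(i, j - 1)] + gap_extend);
    }
  }
  double sM = M[id(n, m)], sX = X[id(n, m)], sY = Y[id(n, m)];
  double score = std::max(sM, std::max(sY, sX));

  // traceback
  std::vector<int> ai, bi;  // 1-based indices, 0 = gap
  int i = n, j = m;
  int state = (sM >= sY && sM >= sX) ? 0 : (sY >= sX ? 2 : 1);
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      double best = std::max(M[id(i, j)], std::max(X[id(i, j)], Y[id(i, j)]));
      if (M[id(i, j)] == best) state = 0;
      else if (Y[id(i, j)] == best) state = 2;
      else state = 1;
    } else if (state == 1) {  // gap in second sequence: consume a_i
      ai.push_back(i); bi.push_back(0);
      double cur = X[id(i, j)];
      --i;
      if (X[id(i, j)] + gap_extend == cur) state = 1;
      else if (Y[id(i, j)] + gap_open == cur &&
               Y[id(i, j)] >= M[id(i, j)]) state = 2;
      else state = 0;
    } else {  // gap in first sequence: consume b_j
      ai.push_back(0); bi.push_back(j);
      double cur = Y[id(i, j)];
      --j;
      if (Y[id(i, j)] + gap_extend == cur) state = 2;
      else if (X[id(i, j)] + gap_open == cur &&
               X[id(i, j)] >= M[id(i, j)]) state = 1;
      else state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(ai.begin(), ai.end()),
                      _["b"] = IntegerVector(bi.begin(), bi.end()));
}
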