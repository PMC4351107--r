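#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment over a precomputed column-score matrix.
//
// S(i,j) is the score of aligning row-object i of A against row-object j of
// B (a substitution score for plain sequences, a mean pairwise column score
// for profiles).  A gap run of length k costs gap_open + (k-1)*gap_extend,
// both passed as non-positive numbers.  Three-state DP (match / gap-in-B /
// gap-in-A); traceback ties resolved diagonal first, then up (consume A),
// then left (consume B), so the path is fully deterministic.
//
// Returns list(score, path) where path is a K x 2 integer matrix of 1-based
// indices into A and B, 0 marking a gap.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".nw_dp")]]
List nw_dp(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    Y(i, 0) = NEG_INF;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = gap_open + (j - 1) * gap_extend;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dm = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = dm + S(i - 1, j - 1);
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                 std::max(X(i - 1, j) + gap_extend,
                          Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                 std::max(X(i, j - 1) + gap_open,
                          Y(i, j - 1) + gap_extend));
    }
  }

  double score = std::max(M(n, m), std::max(X(n, m), Y(n, m)));

  // traceback: state 0 = M (diagonal), 1 = X (up), 2 = Y (left)
  std::vector<int> ai, bj;
  int i = n, j = m;
  int state;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (state == 0) {
      ai.push_back(i); bj.push_back(j);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      ai.push_back(i); bj.push_back(0);
      double cur = X(i, j);
      --i;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      ai.push_back(0); bj.push_back(j);
      double cur = Y(i, j);
      --j;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_open - cur) < 1e-9) state = 1;
      else state = 2;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }

  const int K = (int) ai.size();
  IntegerMatrix path(K, 2);
  for (int k = 0; k < K; ++k) {
    path(k, 0) = ai[K - 1 - k];
    path(k, 1) = bj[K - 1 - k];
  }
  return List::create(_["score"] = score, _["path"] = path);
}
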