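#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with affine gap penalties (Gotoh three-state DP) over a
// precomputed column-score matrix S (n x m): S(i-1, j-1) is the score for
// aligning position i of the first profile with position j of the second.
// A gap of length L costs gap_open + L * gap_ext. Adjacent gaps in opposite
// profiles each open their own gap.
//
// Traceback tie-break (fixed for determinism): diagonal (match/mismatch)
// over gap in the first profile (consume j) over gap in the second
// (consume i).
//
// Returns 1-based index paths (0 = gap) for both profiles plus the score.
// [[Rcpp::export]]
List gotoh_core(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // state 0: i~j aligned; state 1: gap in first (j consumed, i gapped);
  // state 2: gap in second (i consumed, j gapped)
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG); // gap in first
  std::vector<double> X((n + 1) * (m + 1), NEG); // gap in second
  // traceback: predecessor state for each cell/state
  std::vector<unsigned char> tM((n + 1) * (m + 1), 255);
  std::vector<unsigned char> tY((n + 1) * (m + 1), 255);
  std::vector<unsigned char> tX((n + 1) * (m + 1), 255);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -gap_open - gap_ext * j;
    tY[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -gap_open - gap_ext * i;
    tX[at(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: from any state at (i-1, j-1); prefer M, then Y, then X
      {
        unsigned char tb = 0;
        double bm = M[at(i - 1, j - 1)];
        if (Y[at(i - 1, j - 1)] > bm) { bm = Y[at(i - 1, j - 1)]; tb = 1; }
        if (X[at(i - 1, j - 1)] > bm) { bm = X[at(i - 1, j - 1)]; tb = 2; }
        M[at(i, j)] = bm + S(i - 1, j - 1);
        tM[at(i, j)] = tb;
      }
      // Y: gap in first profile, consume j
      {
        double open = M[at(i, j - 1)] - gap_open - gap_ext;
        double ext  = Y[at(i, j - 1)] - gap_ext;
        double openx = X[at(i, j - 1)] - gap_open - gap_ext;
        double best = open; unsigned char tb = 0;
        if (ext > best) { best = ext; tb = 1; }
        if (openx > best) { best = openx; tb = 2; }
        Y[at(i, j)] = best;
        tY[at(i, j)] = tb;
      }
      // X: gap in second profile, consume i
      {
        double open = M[at(i - 1, j)] - gap_open - gap_ext;
        double ext  = X[at(i - 1, j)] - gap_ext;
        double openy = Y[at(i - 1, j)] - gap_open - gap_ext;
        double best = open; unsigned char tb = 0;
        if (ext > best) { best = ext; tb = 2; }
        if (openy > best) { best = openy; tb = 1; }
        X[at(i, j)] = best;
        tX[at(i, j)] = tb;
      }
    }
  }

  // final state: prefer M, then Y, then X
  int state = 0;
  double score = M[at(n, m)];
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 1; }
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 2; }

  std::vector<int> ai, bj;
  ai.reserve(n + m);
  bj.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tM[at(i, j)];
      ai.push_back(i);
      bj.push_back(j);
      --i; --j;
      state = tb;
    } else if (state == 1) {
      unsigned char tb = tY[at(i, j)];
      ai.push_back(0);
      bj.push_back(j);
      --j;
      state = tb;
    } else {
      unsigned char tb = tX[at(i, j)];
      ai.push_back(i);
      bj.push_back(0);
      --i;
      state = tb;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bj),
                      _["score"] = score);
}
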