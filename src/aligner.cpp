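#include <Rcpp.h>
#include <vector>
#include <limits>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP), local
// (Smith-Waterman) or global (Needleman-Wunsch). Sequences arrive as
// 0-based integer codes indexing `submat`. A gap of length L costs
// gap_open + L * gap_extend (both arguments negative), matching the
// Biostrings gapOpening/gapExtension convention up to sign.
//
// Tie-breaking is deterministic: the substitution state wins over gap
// states on equal score; gap-in-y (consume x) wins over gap-in-x.
//
// Returns the optimal score and, when traceback is requested, 1-based
// index vectors of the aligned columns (0 marks a gap in that row).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_codes_cpp(IntegerVector x, IntegerVector y, NumericMatrix submat,
                     double gap_open, double gap_extend, bool global,
                     bool traceback) {
  const int m = x.size(), n = y.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const double gi = gap_open + gap_extend;  // first gap residue
  const double ge = gap_extend;             // each further residue

  std::vector<double> Mprev(n + 1), Mcur(n + 1);
  std::vector<double> Xprev(n + 1), Xcur(n + 1);
  std::vector<double> Yprev(n + 1), Ycur(n + 1);

  // predecessor codes: 0 = fresh start (local) / origin, 1 = M, 2 = X, 3 = Y
  std::vector<unsigned char> tbM, tbX, tbY;
  const size_t stride = (size_t)(n + 1);
  if (traceback) {
    if ((double)(m + 1) * (double)(n + 1) > 6.0e7)
      stop("alignment problem too large for traceback");
    tbM.assign((size_t)(m + 1) * stride, 0);
    tbX.assign((size_t)(m + 1) * stride, 0);
    tbY.assign((size_t)(m + 1) * stride, 0);
  }

  // row 0
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= n; ++j) {
    Xprev[j] = NEG_INF;
    if (global) {
      Mprev[j] = NEG_INF;
      Yprev[j] = gi + ge * (j - 1);
      if (traceback) tbY[j] = (j == 1) ? 1 : 3;
    } else {
      Mprev[j] = 0.0;   // empty prefix: local alignments start anywhere
      Yprev[j] = NEG_INF;
    }
  }

  double best = global ? NEG_INF : 0.0;
  int best_i = 0, best_j = 0, best_state = 1;

  for (int i = 1; i <= m; ++i) {
    Ycur[0] = NEG_INF;
    if (global) {
      Mcur[0] = NEG_INF;
      Xcur[0] = gi + ge * (i - 1);
      if (traceback) tbX[(size_t)i * stride] = (i == 1) ? 1 : 2;
    } else {
      Mcur[0] = 0.0;
      Xcur[0] = NEG_INF;
    }
    const int xi = x[i - 1];
    for (int j = 1; j <= n; ++j) {
      const double s = submat(xi, y[j - 1]);

      // M: substitution ending at (i,j)
      double pred; unsigned char mtb;
      if (global) { pred = Mprev[j - 1]; mtb = 1; }
      else        { pred = 0.0;          mtb = 0; }
      if (global || Mprev[j - 1] > pred) {
        if (Mprev[j - 1] >= pred) { pred = Mprev[j - 1]; mtb = 1; }
      }
      if (Xprev[j - 1] > pred) { pred = Xprev[j - 1]; mtb = 2; }
      if (Yprev[j - 1] > pred) { pred = Yprev[j - 1]; mtb = 3; }
      double mval = pred + s;
      if (!global && mval < 0.0) { mval = 0.0; mtb = 0; }  // empty cell
      Mcur[j] = mval;

      // X: gap in y (consume x)
      double xbest = Mprev[j] + gi; unsigned char xtb = 1;
      if (Xprev[j] + ge > xbest) { xbest = Xprev[j] + ge; xtb = 2; }
      if (Yprev[j] + gi > xbest) { xbest = Yprev[j] + gi; xtb = 3; }
      Xcur[j] = xbest;

      // Y: gap in x (consume y)
      double ybest = Mcur[j - 1] + gi; unsigned char ytb = 1;
      if (Ycur[j - 1] + ge > ybest) { ybest = Ycur[j - 1] + ge; ytb = 3; }
      if (Xcur[j - 1] + gi > ybest) { ybest = Xcur[j - 1] + gi; ytb = 2; }
      Ycur[j] = ybest;

      if (traceback) {
        const size_t off = (size_t)i * stride + j;
        tbM[off] = mtb; tbX[off] = xtb; tbY[off] = ytb;
      }
      if (!global && Mcur[j] > best) {
        best = Mcur[j]; best_i = i; best_j = j; best_state = 1;
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (global) {
    best = Mprev[n]; best_state = 1; best_i = m; best_j = n;
    if (Xprev[n] > best) { best = Xprev[n]; best_state = 2; }
    if (Yprev[n] > best) { best = Yprev[n]; best_state = 3; }
  }

  if (!traceback || (!global && best <= 0.0))
    return List::create(_["score"] = best);

  std::vector<int> xa, ya;
  int i = best_i, j = best_j, state = best_state;
  while (!(global && i == 0 && j == 0)) {
    const size_t off = (size_t)i * stride + j;
    if (state == 1) {
      const unsigned char p = tbM[off];
      xa.push_back(i); ya.push_back(j);
      --i; --j;
      if (!global && p == 0) break;          // local alignment start
      if (global && i == 0 && j == 0) break;
      state = p;
    } else if (state == 2) {
      const unsigned char p = tbX[off];
      xa.push_back(i); ya.push_back(0);
      --i;
      state = p;
    } else {
      const unsigned char p = tbY[off];
      xa.push_back(0); ya.push_back(j);
      --j;
      state = p;
    }
    if (i < 0 || j < 0) stop("traceback underflow");
  }
  std::reverse(xa.begin(), xa.end());
  std::reverse(ya.begin(), ya.end());
  return List::create(_["score"] = best,
                      _["x_idx"] = IntegerVector(xa.begin(), xa.end()),
                      _["y_idx"] = IntegerVector(ya.begin(), ya.end()));
}
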