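#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap Smith-Waterman over integer-encoded protein sequences.
// Gotoh three-state recursion; a gap of length L costs open + L * extend
// (BLAST convention: gapOpening 11, gapExtension 1 -> an L-gap costs 11 + L).
// Integer DP (substitution scores and penalties are integral); traceback is
// kept so callers get the aligned strings and span coordinates.

static const int NEG = -(1 << 28);

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix subst,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  if (m == 0 || n == 0) {
    return List::create(_["score"] = 0.0,
                        _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0,
                        _["qaln"] = IntegerVector(0),
                        _["taln"] = IntegerVector(0));
  }
  const int ns = subst.nrow();
  const int *S = subst.begin();
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> tcol(n);
  for (int j = 0; j < n; ++j) tcol[j] = ns * t[j];
  std::vector<int> M(n + 1, 0), X(n + 1, NEG);
  // traceback: M: 0 stop, 1 diag, 2 from X, 3 from Y; X/Y: 1 = opened from M
  std::vector<unsigned char> tbM((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbX((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbY((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  int *Mv = M.data(), *Xv = X.data();
  const int *tc = tcol.data();

  for (int i = 1; i <= m; ++i) {
    const int *Sq = S + q[i - 1];
    unsigned char *tM = tbM.data() + (size_t)i * (n + 1);
    unsigned char *tX = tbX.data() + (size_t)i * (n + 1);
    unsigned char *tY = tbY.data() + (size_t)i * (n + 1);
    int Mdiag = Mv[0];
    int Yprev = NEG;
    for (int j = 1; j <= n; ++j) {
      const int x_open = Mv[j] - go, x_ext = Xv[j] - ge;
      int xv; unsigned char xb;
      if (x_open >= x_ext) { xv = x_open; xb = 1; } else { xv = x_ext; xb = 0; }
      const int y_open = Mv[j - 1] - go, y_ext = Yprev - ge;
      int yv; unsigned char yb;
      if (y_open >= y_ext) { yv = y_open; yb = 1; } else { yv = y_ext; yb = 0; }
      int mv = Mdiag + Sq[tc[j - 1]];
      unsigned char tb = 1;
      if (xv > mv) { mv = xv; tb = 2; }
      if (yv > mv) { mv = yv; tb = 3; }
      if (mv <= 0) { mv = 0; tb = 0; }
      Mdiag = Mv[j];
      Mv[j] = mv; Xv[j] = xv; Yprev = yv;
      tM[j] = tb; tX[j] = xb; tY[j] = yb;
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj) in state M
  std::vector<int> qa, ta;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
  while (i > 0 && j > 0) {
    size_t row = (size_t)i * (n + 1);
    if (state == 0) {
      unsigned char tb = tbM[row + j];
      if (tb == 0) break;
      if (tb == 1) { qa.push_back(q[i - 1]); ta.push_back(t[j - 1]); --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      unsigned char tb = tbX[row + j];
      qa.push_back(q[i - 1]); ta.push_back(-1); --i;
      if (tb == 1) state = 0;
    } else {
      unsigned char tb = tbY[row + j];
      qa.push_back(-1); ta.push_back(t[j - 1]); --j;
      if (tb == 1) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = (double)best,
                      _["qstart"] = i + 1, _["qend"] = bi,
                      _["tstart"] = j + 1, _["tend"] = bj,
                      _["qaln"] = wrap(qa), _["taln"] = wrap(ta));
}

// Score + best-cell endpoint scan (no traceback): the fast whole-frame pass.
// Returns c(score, qend, tend) with 1-based inclusive end coordinates.
// [[Rcpp::export(name = ".sw_score_end_cpp")]]
NumericVector sw_score_end_cpp(IntegerVector q, IntegerVector t,
                               IntegerMatrix subst,
                               int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  NumericVector out(3);
  if (m == 0 || n == 0) return out;
  const int ns = subst.nrow();
  const int *S = subst.begin();
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> tcol(n);
  for (int j = 0; j < n; ++j) tcol[j] = ns * t[j];
  std::vector<int> M(n + 1, 0), X(n + 1, NEG);
  int best = 0, bi = 0, bj = 0;
  int *Mv = M.data(), *Xv = X.data();
  const int *tc = tcol.data();
  for (int i = 1; i <= m; ++i) {
    const int *Sq = S + q[i - 1];
    int Mdiag = Mv[0];
    int Yprev = NEG;
    for (int j = 1; j <= n; ++j) {
      const int xv = std::max(Mv[j] - go, Xv[j] - ge);
      const int yv = std::max(Mv[j - 1] - go, Yprev - ge);
      int mv = Mdiag + Sq[tc[j - 1]];
      if (xv > mv) mv = xv;
      if (yv > mv) mv = yv;
      if (mv < 0) mv = 0;
      Mdiag = Mv[j];
      Mv[j] = mv; Xv[j] = xv; Yprev = yv;
      if (mv > best) { best = mv; bi = i; bj = j; }
    }
  }
  out[0] = best; out[1] = bi; out[2] = bj;
  return out;
}

// Score-only scan (no traceback): used for negative-bait screening.
// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector q, IntegerVector t, IntegerMatrix subst,
                    int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  if (m == 0 || n == 0) return 0.0;
  const int ns = subst.nrow();
  const int *S = subst.begin();
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> tcol(n);
  for (int j = 0; j < n; ++j) tcol[j] = ns * t[j];
  std::vector<int> M(n + 1, 0), X(n + 1, NEG);
  int best = 0;
  int *Mv = M.data(), *Xv = X.data();
  const int *tc = tcol.data();
  for (int i = 1; i <= m; ++i) {
    const int *Sq = S + q[i - 1];
    int Mdiag = Mv[0];
    int Yprev = NEG;
    for (int j = 1; j <= n; ++j) {
      const int xv = std::max(Mv[j] - go, Xv[j] - ge);
      const int yv = std::max(Mv[j - 1] - go, Yprev - ge);
      int mv = Mdiag + Sq[tc[j - 1]];
      if (xv > mv) mv = xv;
      if (yv > mv) mv = yv;
      if (mv < 0) mv = 0;
      Mdiag = Mv[j];
      Mv[j] = mv; Xv[j] = xv; Yprev = yv;
      if (mv > best) best = mv;
    }
  }
  return (double)best;
}

// Global (Needleman-Wunsch) affine-gap alignment, end gaps penalized.
// Returns score and the two aligned integer strings (-1 = gap).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix subst,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = t.size();
  const int ns = subst.nrow();
  const int *S = subst.begin();
  const int go = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> tcol(n);
  for (int j = 0; j < n; ++j) tcol[j] = ns * t[j];
  std::vector<int> M(n + 1), X(n + 1), Y(n + 1);
  std::vector<unsigned char> tbM((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbX((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbY((size_t)(m + 1) * (n + 1), 0);
  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    M[j] = NEG; X[j] = NEG;
    Y[j] = -(go + ge * (j - 1));
    tbY[j] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    unsigned char *tM = tbM.data() + (size_t)i * (n + 1);
    unsigned char *tX = tbX.data() + (size_t)i * (n + 1);
    unsigned char *tY = tbY.data() + (size_t)i * (n + 1);
    const int *Sq = S + q[i - 1];
    int Mdiag = M[0];   // best(i-1, 0)
    int Xdiag = X[0], Ydiag = Y[0];
    // column 0
    int Mprev0 = M[0];
    M[0] = NEG; Y[0] = NEG;
    X[0] = -(go + ge * (i - 1));
    tX[0] = (i == 1) ? 1 : 0;
    int Yprev = NEG;
    int bprev = std::max(std::max(M[0], X[0]), Y[0]); // best(i, 0)
    (void)Mprev0; (void)Xdiag; (void)Ydiag; (void)bprev;
    for (int j = 1; j <= n; ++j) {
      // X: gap in target (consume query), from row i-1
      const int x_open = M[j] - go, x_ext = X[j] - ge;
      int xv; unsigned char xb;
      if (x_open >= x_ext) { xv = x_open; xb = 1; } else { xv = x_ext; xb = 0; }
      // allow opening from Y as well (gap switch)
      const int x_fromY = Y[j] - go;
      if (x_fromY > xv) { xv = x_fromY; xb = 2; }
      // Y: gap in query (consume target), from column j-1 of row i
      const int y_open = M[j - 1] - go, y_ext = Yprev - ge;
      int yv; unsigned char yb;
      if (y_open >= y_ext) { yv = y_open; yb = 1; } else { yv = y_ext; yb = 0; }
      const int y_fromX = X[j - 1] - go;
      if (y_fromX > yv) { yv = y_fromX; yb = 2; }
      // M: diagonal from best state at (i-1, j-1)
      int dbest = Mdiag; unsigned char db = 1;
      if (Xdiag > dbest) { dbest = Xdiag; db = 2; }
      if (Ydiag > dbest) { dbest = Ydiag; db = 3; }
      const int mv = (dbest <= NEG / 2) ? NEG : dbest + Sq[tcol[j - 1]];
      Mdiag = M[j]; Xdiag = X[j]; Ydiag = Y[j];
      M[j] = mv; X[j] = xv; Y[j] = yv; Yprev = yv;
      tM[j] = db; tX[j] = xb; tY[j] = yb;
    }
  }
  // traceback from the best end state at (m, n)
  int state = 0; int bestv = M[n];
  if (X[n] > bestv) { bestv = X[n]; state = 1; }
  if (Y[n] > bestv) { bestv = Y[n]; state = 2; }
  std::vector<int> qa, ta;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    size_t row = (size_t)i * (n + 1);
    if (state == 0) {
      unsigned char db = tbM[row + j];
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j;
      state = (db == 1) ? 0 : (db == 2 ? 1 : 2);
    } else if (state == 1) {
      unsigned char xb = tbX[row + j];
      qa.push_back(q[i - 1]); ta.push_back(-1); --i;
      state = (xb == 1) ? 0 : (xb == 2 ? 2 : 1);
    } else {
      unsigned char yb = tbY[row + j];
      qa.push_back(-1); ta.push_back(t[j - 1]); --j;
      state = (yb == 1) ? 0 : (yb == 2 ? 1 : 2);
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = (double)bestv,
                      _["qaln"] = wrap(qa), _["taln"] = wrap(ta));
}
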