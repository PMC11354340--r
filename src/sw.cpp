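#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh three-state DP).
//
// Gap model follows the NCBI convention: a gap of length g costs
// gap_open + g * gap_extend.  Two passes: a linear-memory score pass over
// the whole subject, then a traceback pass restricted to a window that is
// guaranteed to contain the optimal alignment's subject span.
//
// Determinism: the best-scoring end cell is the first encountered scanning
// query positions then subject positions in ascending order (strictly-
// greater replacement); traceback prefers stopping, then the diagonal,
// then gap closure over gap extension.  Among co-optimal alignments this
// yields a single reproducible choice.
//
// q and s are 0-based indices into mat.  Alignment columns are returned
// as parallel code vectors (1 = consume a residue, 2 = gap) from which the
// R wrapper builds the aligned strings.

static const int NEG = -1000000000;

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int m = q.size(), n = s.size();
  List empty = List::create(_["score"] = 0);
  if (m == 0 || n == 0) return empty;
  const int oe = gap_open + gap_extend;

  // flatten the score matrix row-major for fast row access
  const int nres = mat.ncol();
  std::vector<int> flat((size_t)mat.nrow() * nres);
  for (int a = 0; a < mat.nrow(); ++a)
    for (int b = 0; b < nres; ++b)
      flat[(size_t)a * nres + b] = mat(a, b);
  const int *sp = s.begin();

  // pass 1: linear-memory score pass
  // M = diagonal state, X = gap in query (consumes subject),
  // Y = gap in subject (consumes query)
  std::vector<int> Mprev(n + 1, 0), Xprev(n + 1, NEG), Yprev(n + 1, NEG);
  std::vector<int> Mcur(n + 1, 0), Xcur(n + 1, NEG), Ycur(n + 1, NEG);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0; Xcur[0] = NEG; Ycur[0] = NEG;
    const int *row = &flat[(size_t)q[i - 1] * nres];
    const int *Mp = Mprev.data(), *Xp = Xprev.data(), *Yp = Yprev.data();
    int *Mc = Mcur.data(), *Xc = Xcur.data(), *Yc = Ycur.data();
    for (int j = 1; j <= n; ++j) {
      int pre = Mp[j - 1];
      if (Xp[j - 1] > pre) pre = Xp[j - 1];
      if (Yp[j - 1] > pre) pre = Yp[j - 1];
      if (pre < 0) pre = 0;
      const int Mv = row[sp[j - 1]] + pre;
      int Xv = Mc[j - 1] - oe;
      const int xe = Xc[j - 1] - gap_extend;
      if (xe > Xv) Xv = xe;
      int Yv = Mp[j] - oe;
      const int ye = Yp[j] - gap_extend;
      if (ye > Yv) Yv = ye;
      Mc[j] = Mv; Xc[j] = Xv; Yc[j] = Yv;
      if (Mv > best) { best = Mv; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  if (best <= 0) return empty;

  // pass 2: windowed traceback.  The optimal alignment's subject span is
  // at most m (columns that also consume query) plus the longest
  // affordable subject-consuming gap run.
  int maxsub = 0;
  for (int a = 0; a < mat.nrow(); ++a)
    for (int b = 0; b < mat.ncol(); ++b)
      if (mat(a, b) > maxsub) maxsub = mat(a, b);
  long gmax = ((long)m * maxsub) / (gap_extend > 0 ? gap_extend : 1) + 1;
  long lo = (long)bj - m - gmax - 1;
  const int j0 = lo < 0 ? 0 : (int)lo;    // 0-based subject offset
  const int w = bj - j0;                  // window width

  std::vector<std::vector<int> > M(m + 1, std::vector<int>(w + 1, 0));
  std::vector<std::vector<int> > X(m + 1, std::vector<int>(w + 1, NEG));
  std::vector<std::vector<int> > Y(m + 1, std::vector<int>(w + 1, NEG));
  std::vector<std::vector<unsigned char> > tbM(m + 1, std::vector<unsigned char>(w + 1, 0));
  std::vector<std::vector<unsigned char> > tbX(m + 1, std::vector<unsigned char>(w + 1, 0));
  std::vector<std::vector<unsigned char> > tbY(m + 1, std::vector<unsigned char>(w + 1, 0));

  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= w; ++j) {
      // M predecessor preference on ties: start > diag-M > diag-X > diag-Y
      int pre = 0; unsigned char ch = 0;
      if (M[i - 1][j - 1] > pre) { pre = M[i - 1][j - 1]; ch = 1; }
      if (X[i - 1][j - 1] > pre) { pre = X[i - 1][j - 1]; ch = 2; }
      if (Y[i - 1][j - 1] > pre) { pre = Y[i - 1][j - 1]; ch = 3; }
      M[i][j] = mat(qi, s[j0 + j - 1]) + pre; tbM[i][j] = ch;
      const int oM = M[i][j - 1] - oe, eX = X[i][j - 1] - gap_extend;
      if (oM >= eX) { X[i][j] = oM; tbX[i][j] = 1; } else { X[i][j] = eX; tbX[i][j] = 2; }
      const int oY = M[i - 1][j] - oe, eY = Y[i - 1][j] - gap_extend;
      if (oY >= eY) { Y[i][j] = oY; tbY[i][j] = 1; } else { Y[i][j] = eY; tbY[i][j] = 2; }
    }
  }
  const int ei = bi, ej = bj - j0;
  if (M[ei][ej] != best) stop("internal error: traceback window missed optimum");

  std::vector<int> qrev, srev;  // column codes, reversed
  int i = ei, j = ej, state = 0;  // 0 = M, 1 = X, 2 = Y
  int qs = ei, ss = ej;
  while (true) {
    if (state == 0) {
      qrev.push_back(1); srev.push_back(1);
      const unsigned char ch = tbM[i][j];
      qs = i; ss = j;
      --i; --j;
      if (ch == 0) break;
      state = (ch == 1) ? 0 : (ch == 2 ? 1 : 2);
    } else if (state == 1) {    // gap in query, consumes subject
      qrev.push_back(2); srev.push_back(1);
      const unsigned char ch = tbX[i][j];
      --j;
      state = (ch == 1) ? 0 : 1;
    } else {                    // gap in subject, consumes query
      qrev.push_back(1); srev.push_back(2);
      const unsigned char ch = tbY[i][j];
      --i;
      state = (ch == 1) ? 0 : 2;
    }
  }
  IntegerVector qcols(qrev.rbegin(), qrev.rend());
  IntegerVector scols(srev.rbegin(), srev.rend());

  return List::create(
    _["score"] = best,
    _["qstart"] = qs, _["qend"] = ei,
    _["sstart"] = j0 + ss, _["send"] = j0 + ej,
    _["qcols"] = qcols, _["scols"] = scols);
}
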