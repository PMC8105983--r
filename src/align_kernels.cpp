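#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Amino-acid alphabet shared with the R side; index -1 encodes X/unknown.
static const char AA20[] = "ACDEFGHIKLMNPQRSTVWY";

static std::vector<int> encode_aa(const std::string &s) {
  static int lut[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) lut[i] = -1;
    for (int i = 0; i < 20; ++i) lut[(unsigned char)AA20[i]] = i;
    init = true;
  }
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

// Local (Smith-Waterman-style) alignment of a position-specific scoring
// matrix (rows = profile match columns, cols = 20 residues, bits) against a
// protein.  Affine gaps: a gap of length k costs open + k * ext bits.
// Residues outside the 20-letter alphabet (X, etc.) score x_score, which is
// negative so they never contribute positively to a hit.
// [[Rcpp::export(name = ".profile_local_align")]]
List profile_local_align(NumericMatrix pssm, std::string protein,
                         double gap_open, double gap_ext,
                         double x_score, bool traceback) {
  const int L = pssm.nrow();
  std::vector<int> q = encode_aa(protein);
  const int n = (int)q.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext; // cost of opening a length-1 gap

  std::vector<double> Mprev(n + 1, 0.0), Mcur(n + 1, 0.0);
  std::vector<double> Xprev(n + 1, NEG), Xcur(n + 1, NEG); // gap in protein
  std::vector<double> Yprev(n + 1, NEG), Ycur(n + 1, NEG); // gap in profile
  // traceback state: 0 stop, 1 diag-from-M, 2 diag-from-X, 3 diag-from-Y
  std::vector<signed char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((size_t)(L + 1) * (n + 1), 0);
    tbX.assign((size_t)(L + 1) * (n + 1), 0);
    tbY.assign((size_t)(L + 1) * (n + 1), 0);
  }
  double best = 0.0; int bi = 0, bj = 0;

  for (int i = 1; i <= L; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    double yleft = NEG;
    for (int j = 1; j <= n; ++j) {
      double s = (q[j - 1] >= 0) ? pssm(i - 1, q[j - 1]) : x_score;
      // M: profile column i aligned to residue j
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      // a zero-valued predecessor is a fresh local start, not a path
      double d = 0.0; signed char st = 0;
      if (dM > d) { d = dM; st = 1; }
      if (dX > d) { d = dX; st = 2; }
      if (dY > d) { d = dY; st = 3; }
      double m = d + s;
      if (m < 0) { m = 0; st = 0; }
      // X: consume profile column i without a residue (deletion in protein)
      double xo = Mprev[j] - gi, xe = Xprev[j] - gap_ext;
      double x; signed char sx;
      if (xo >= xe) { x = xo; sx = 1; } else { x = xe; sx = 2; }
      // Y: consume residue j without a profile column (insertion)
      double yo = Mcur[j - 1] - gi, ye = yleft - gap_ext;
      double y; signed char sy;
      if (yo >= ye) { y = yo; sy = 1; } else { y = ye; sy = 3; }
      Mcur[j] = m; Xcur[j] = x; Ycur[j] = y; yleft = y;
      if (traceback) {
        tbM[(size_t)i * (n + 1) + j] = st;
        tbX[(size_t)i * (n + 1) + j] = sx;
        tbY[(size_t)i * (n + 1) + j] = sy;
      }
      if (m > best) { best = m; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (!traceback || best <= 0.0)
    return List::create(_["bits"] = best,
                        _["p_start"] = NA_INTEGER, _["p_end"] = NA_INTEGER,
                        _["q_start"] = NA_INTEGER, _["q_end"] = NA_INTEGER);

  // walk back from the best M cell to the first cell entered from 0
  int i = bi, j = bj, state = 0; // 0 = in M
  int pi_end = bi, qj_end = bj, pi_start = bi, qj_start = bj;
  while (true) {
    if (state == 0) {
      signed char st = tbM[(size_t)i * (n + 1) + j];
      pi_start = i; qj_start = j;
      --i; --j;
      if (st == 0) break;
      state = (st == 1) ? 0 : (st == 2 ? 1 : 2);
    } else if (state == 1) { // X: came from row above, same column
      signed char st = tbX[(size_t)i * (n + 1) + j];
      --i;
      state = (st == 1) ? 0 : 1;
    } else {               // Y: came from same row, previous column
      signed char st = tbY[(size_t)i * (n + 1) + j];
      --j;
      state = (st == 1) ? 0 : 2;
    }
  }
  return List::create(_["bits"] = best,
                      _["p_start"] = pi_start - 1, _["p_end"] = pi_end,
                      _["q_start"] = qj_start - 1, _["q_end"] = qj_end);
}

// Score many proteins against one PSSM without traceback (calibration and
// first-pass scanning).  Returns the vector of best local scores in bits.
// [[Rcpp::export(name = ".profile_score_many")]]
NumericVector profile_score_many(NumericMatrix pssm, CharacterVector proteins,
                                 double gap_open, double gap_ext,
                                 double x_score) {
  const int N = proteins.size();
  const int L = pssm.nrow();
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext;
  // flatten to row-major so the inner loop walks contiguous memory
  std::vector<double> S((size_t)L * 21);
  for (int i = 0; i < L; ++i) {
    for (int a = 0; a < 20; ++a) S[(size_t)i * 21 + a] = pssm(i, a);
    S[(size_t)i * 21 + 20] = x_score; // X / unknown residue
  }
  NumericVector out(N);
  std::vector<double> M1, M2, X1, X2, Y1, Y2;
  for (int k = 0; k < N; ++k) {
    std::vector<int> q = encode_aa(as<std::string>(proteins[k]));
    const int n = (int)q.size();
    for (int j = 0; j < n; ++j) if (q[j] < 0) q[j] = 20;
    M1.assign(n + 1, 0.0); M2.assign(n + 1, 0.0);
    X1.assign(n + 1, NEG); X2.assign(n + 1, NEG);
    Y1.assign(n + 1, NEG); Y2.assign(n + 1, NEG);
    double *Mp = M1.data(), *Mc = M2.data(), *Xp = X1.data(),
           *Xc = X2.data(), *Yp = Y1.data(), *Yc = Y2.data();
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      const double *row = &S[(size_t)(i - 1) * 21];
      Mc[0] = 0.0; Xc[0] = NEG; Yc[0] = NEG;
      double yleft = NEG;
      for (int j = 1; j <= n; ++j) {
        double d = Mp[j - 1];
        if (Xp[j - 1] > d) d = Xp[j - 1];
        if (Yp[j - 1] > d) d = Yp[j - 1];
        if (d < 0.0) d = 0.0;
        double m = d + row[q[j - 1]];
        if (m < 0.0) m = 0.0;
        double x = Mp[j] - gi, xe = Xp[j] - gap_ext;
        if (xe > x) x = xe;
        double y = Mc[j - 1] - gi, ye = yleft - gap_ext;
        if (ye > y) y = ye;
        Mc[j] = m; Xc[j] = x; Yc[j] = y; yleft = y;
        if (m > best) best = m;
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[k] = best;
  }
  return out;
}

// Global (Needleman-Wunsch) alignment with affine gaps and a residue
// substitution matrix.  a and b are 1-based index vectors into submat.
// Gap of length k costs open + k * ext.  Ties are broken preferring
// match > deletion (gap in b) > insertion (gap in a).
// Returns an (ncol x 2) matrix of 1-based positions, 0 marking a gap.
// [[Rcpp::export(name = ".nw_align")]]
IntegerMatrix nw_align(IntegerVector a, IntegerVector b, NumericMatrix submat,
                       double gap_open, double gap_ext) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  const double gi = gap_open + gap_ext;
  std::vector<double> M((size_t)(m + 1) * (n + 1), NEG);
  std::vector<double> X(M), Y(M); // X: gap in b (consume a); Y: gap in a
  std::vector<signed char> tM(M.size(), 0), tX(M.size(), 0), tY(M.size(), 0);
  auto at = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[at(i, 0)] = -(gap_open + gap_ext * i);
    tX[at(i, 0)] = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= n; ++j) {
    Y[at(0, j)] = -(gap_open + gap_ext * j);
    tY[at(0, j)] = (j == 1) ? 1 : 3;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = submat(a[i - 1] - 1, b[j - 1] - 1);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      double d = dM; signed char st = 1;            // prefer match
      if (dX > d) { d = dX; st = 2; }
      if (dY > d) { d = dY; st = 3; }
      M[at(i, j)] = d + s; tM[at(i, j)] = st;
      double xo = M[at(i - 1, j)] - gi, xe = X[at(i - 1, j)] - gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tX[at(i, j)] = 1; }
      else          { X[at(i, j)] = xe; tX[at(i, j)] = 2; }
      double yo = M[at(i, j - 1)] - gi, ye = Y[at(i, j - 1)] - gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = ye; tY[at(i, j)] = 3; }
    }
  }
  // choose final state: match > deletion > insertion on ties
  double fM = M[at(m, n)], fX = X[at(m, n)], fY = Y[at(m, n)];
  int state = 0; double bestv = fM;
  if (fX > bestv) { bestv = fX; state = 1; }
  if (fY > bestv) { bestv = fY; state = 2; }

  std::vector<int> pa, pb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char st = tM[at(i, j)];
      pa.push_back(i); pb.push_back(j); --i; --j;
      state = (st == 1) ? 0 : (st == 2 ? 1 : 2);
    } else if (state == 1) {
      signed char st = tX[at(i, j)];
      pa.push_back(i); pb.push_back(0); --i;
      state = (st == 1) ? 0 : 1;
    } else {
      signed char st = tY[at(i, j)];
      pa.push_back(0); pb.push_back(j); --j;
      state = (st == 1) ? 0 : 2;
    }
  }
  const int len = (int)pa.size();
  IntegerMatrix out(len, 2);
  for (int k = 0; k < len; ++k) {
    out(k, 0) = pa[len - 1 - k];
    out(k, 1) = pb[len - 1 - k];
  }
  out.attr("score") = bestv;
  return out;
}
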