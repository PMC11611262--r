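#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh), returning
// percent identity = matches / alignment length (gaps included).
// subst is a square scoring matrix whose dimnames cover all residue letters.

struct Scoring {
  std::vector<double> m;  // 128x128 lookup by ASCII
  double gap_open, gap_ext;
};

static double nw_pid(const std::string &a, const std::string &b,
                     const Scoring &sc) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e30;
  // DP with affine gaps; traceback to count matches and alignment length.
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  std::vector<signed char> tbM((n + 1) * (m + 1), 0), tbX((n + 1) * (m + 1), 0),
      tbY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -sc.gap_open - sc.gap_ext * i;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;  // 0: from M, 1: extend
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -sc.gap_open - sc.gap_ext * j;
    tbY[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sc.m[(unsigned char)a[i - 1] * 128 + (unsigned char)b[j - 1]];
      // M: diagonal
      double mm = M[at(i - 1, j - 1)], mx = X[at(i - 1, j - 1)],
             my = Y[at(i - 1, j - 1)];
      int tb = 0; double best = mm;
      if (mx > best) { best = mx; tb = 1; }
      if (my > best) { best = my; tb = 2; }
      M[at(i, j)] = best + s; tbM[at(i, j)] = (signed char)tb;
      // X: gap in b (consume a[i])
      double xo = M[at(i - 1, j)] - sc.gap_open - sc.gap_ext,
             xe = X[at(i - 1, j)] - sc.gap_ext;
      if (xo >= xe) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else          { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      // Y: gap in a (consume b[j])
      double yo = M[at(i, j - 1)] - sc.gap_open - sc.gap_ext,
             ye = Y[at(i, j - 1)] - sc.gap_ext;
      if (yo >= ye) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else          { Y[at(i, j)] = ye; tbY[at(i, j)] = 1; }
    }
  }
  // traceback from the best terminal state
  int state = 0;
  double best = M[at(n, m)];
  if (X[at(n, m)] > best) { best = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; state = 2; }
  int i = n, j = m; long matches = 0, alen = 0;
  while (i > 0 && j > 0) {
    ++alen;
    if (state == 0) {
      int tb = tbM[at(i, j)];
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
      state = tb;
    } else if (state == 1) {
      int tb = tbX[at(i, j)];
      --i;
      state = (tb == 1) ? 1 : 0;
    } else {
      int tb = tbY[at(i, j)];
      --j;
      state = (tb == 1) ? 2 : 0;
    }
  }
  alen += i + j;  // leading terminal gap, if any
  return alen > 0 ? (double)matches / (double)alen : 0.0;
}

// [[Rcpp::export(name = ".nw_identity_cpp")]]
NumericVector nw_identity_cpp(CharacterVector patterns, std::string subject,
                              NumericMatrix subst, double gap_open,
                              double gap_ext) {
  Scoring sc;
  sc.m.assign(128 * 128, 0.0);
  sc.gap_open = gap_open;
  sc.gap_ext = gap_ext;
  CharacterVector rn = rownames(subst), cn = colnames(subst);
  for (int i = 0; i < subst.nrow(); ++i) {
    unsigned char ri = (unsigned char)std::string(rn[i])[0];
    for (int j = 0; j < subst.ncol(); ++j) {
      unsigned char cj = (unsigned char)std::string(cn[j])[0];
      sc.m[ri * 128 + cj] = subst(i, j);
    }
  }
  int n = patterns.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = nw_pid(std::string(patterns[i]), subject, sc);
  }
  return out;
}
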