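// Affine-gap pairwise alignment (Gotoh three-state DP) over an arbitrary
// scored alphabet, global (Needleman-Wunsch) and local (Smith-Waterman)
// variants with full traceback. A gap of length L costs open + L * extend.
#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Tb { std::vector<signed char> M, X, Y; };

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b, NumericMatrix submat,
                 double gap_open, double gap_ext, std::string mode) {
  const bool local = (mode == "local");
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // char -> row index of the substitution matrix
  std::vector<int> idx(256, -1);
  CharacterVector rn = rownames(submat);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    idx[(unsigned char)s[0]] = i;
    idx[(unsigned char)std::tolower(s[0])] = i;
  }
  for (int i = 0; i < n; ++i)
    if (idx[(unsigned char)a[i]] < 0)
      stop("non-IUPAC character '%s' in sequence a", std::string(1, a[i]));
  for (int j = 0; j < m; ++j)
    if (idx[(unsigned char)b[j]] < 0)
      stop("non-IUPAC character '%s' in sequence b", std::string(1, b[j]));

  const int W = m + 1;
  // state matrices, row-major over (i, j)
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: for M, 0 = diag-from-M, 1 = diag-from-X, 2 = diag-from-Y,
  // 3 = local start; for X (gap in b, consumes a): 0 = open-from-M,
  // 1 = extend; for Y (gap in a, consumes b): likewise.
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1),
      tY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = local ? 0.0 : -(gap_open + gap_ext * i);
    tX[i * W] = (i == 1) ? 0 : 1;
    if (local) { M[i * W] = 0.0; tM[i * W] = 3; }
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = local ? 0.0 : -(gap_open + gap_ext * j);
    tY[j] = (j == 1) ? 0 : 1;
    if (local) { M[j] = 0.0; tM[j] = 3; }
  }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, up = (i - 1) * W + j, lf = c - 1,
                dg = up - 1;
      // X: gap in b (a aligned to '-'), vertical move
      double xo = M[up] - (gap_open + gap_ext), xe = X[up] - gap_ext;
      if (xo >= xe) { X[c] = xo; tX[c] = 0; } else { X[c] = xe; tX[c] = 1; }
      // Y: gap in a, horizontal move
      double yo = M[lf] - (gap_open + gap_ext), ye = Y[lf] - gap_ext;
      if (yo >= ye) { Y[c] = yo; tY[c] = 0; } else { Y[c] = ye; tY[c] = 1; }
      // M: diagonal
      double s = submat(ai, idx[(unsigned char)b[j - 1]]);
      double mm = M[dg], mx = X[dg], my = Y[dg];
      double dbest = mm; signed char dt = 0;
      if (mx > dbest) { dbest = mx; dt = 1; }
      if (my > dbest) { dbest = my; dt = 2; }
      double val = dbest + s; signed char t = dt;
      if (local && val < 0.0) { val = 0.0; t = 3; }
      M[c] = val; tM[c] = t;
      if (local) {
        // local alignments end in a match/mismatch state
        if (M[c] > best) { best = M[c]; bi = i; bj = j; }
      }
    }
  }

  int i, j; signed char state; double score;
  if (local) {
    score = best; i = bi; j = bj; state = 0;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0, _["a_aln"] = "",
                          _["b_aln"] = "", _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0);
    }
  } else {
    const int c = n * W + m;
    score = M[c]; state = 0;
    if (X[c] > score) { score = X[c]; state = 1; }
    if (Y[c] > score) { score = Y[c]; state = 2; }
    i = n; j = m;
  }

  std::string aa, bb;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {            // M
      if (local && tM[c] == 3) break;
      if (i == 0 || j == 0) {    // global boundary: switch into gap states
        if (i > 0) state = 1; else state = 2;
        continue;
      }
      signed char t = tM[c];
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
      --i; --j;
      if (local && (i == 0 || j == 0)) break;
      state = (t == 1) ? 1 : (t == 2) ? 2 : 0;
    } else if (state == 1) {     // X: a vs gap
      aa.push_back(a[i - 1]); bb.push_back('-');
      signed char t = tX[c];
      --i;
      state = (t == 1) ? 1 : 0;
      if (local && i == 0) break;
    } else {                     // Y: gap vs b
      aa.push_back('-'); bb.push_back(b[j - 1]);
      signed char t = tY[c];
      --j;
      state = (t == 1) ? 2 : 0;
      if (local && j == 0) break;
    }
    if (local && state == 0 && (i == 0 || j == 0)) break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  int a_start = local ? i + 1 : 1, a_end = local ? bi : n;
  int b_start = local ? j + 1 : 1, b_end = local ? bj : m;
  return List::create(_["score"] = score, _["a_aln"] = aa, _["b_aln"] = bb,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}
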