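#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh).  A gap of length L
// costs gap_open + gap_extend * (L - 1); end gaps are penalized (true
// global alignment).  Traceback tie-breaking is deterministic: prefer the
// diagonal (match/mismatch), then up (gap in sequence b), then left (gap in
// sequence a).
//
// States: M = a[i] aligned to b[j]; E = gap in b (consumes a, "up");
// F = gap in a (consumes b, "left").

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix sub,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // score matrices, (n+1) x (m+1), row-major flattened
  std::vector<double> M((n + 1) * (m + 1), NEG), E(M), F(M);
  // traceback: which state each cell's best move came from (0=M,1=E,2=F)
  std::vector<unsigned char> tbM(M.size(), 0), tbE(M.size(), 0), tbF(M.size(), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    E[at(i, 0)] = -gap_open - gap_extend * (i - 1);
    tbE[at(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    F[at(0, j)] = -gap_open - gap_extend * (j - 1);
    tbF[at(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j), up = at(i - 1, j), lf = at(i, j - 1),
                di = at(i - 1, j - 1);
      // E: gap in b, consume a[i]
      double eo = std::max(M[up], F[up]) - gap_open;
      double ee = E[up] - gap_extend;
      if (ee >= eo) { E[ij] = ee; tbE[ij] = 1; }
      else { E[ij] = eo; tbE[ij] = (M[up] >= F[up]) ? 0 : 2; }
      // F: gap in a, consume b[j]
      double fo = std::max(M[lf], E[lf]) - gap_open;
      double fe = F[lf] - gap_extend;
      if (fe >= fo) { F[ij] = fe; tbF[ij] = 2; }
      else { F[ij] = fo; tbF[ij] = (M[lf] >= E[lf]) ? 0 : 1; }
      // M: diagonal
      double s = sub(a[i - 1], b[j - 1]);
      double best = M[di]; unsigned char src = 0;
      if (E[di] > best) { best = E[di]; src = 1; }
      if (F[di] > best) { best = F[di]; src = 2; }
      M[ij] = best + s; tbM[ij] = src;
    }
  }

  const int end = at(n, m);
  double score = M[end]; int state = 0;           // prefer diagonal,
  if (E[end] > score) { score = E[end]; state = 1; } // then up,
  if (F[end] > score) { score = F[end]; state = 2; } // then left

  std::vector<int> ga, gb;  // 0 = gap, else 1-based index into a / b
  int i = n, j = m, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int src = tbM[at(i, j)];
      ga.push_back(i); gb.push_back(j); --i; --j; st = src;
    } else if (st == 1) {
      int src = tbE[at(i, j)];
      ga.push_back(i); gb.push_back(0); --i; st = src;
    } else {
      int src = tbF[at(i, j)];
      ga.push_back(0); gb.push_back(j); --j; st = src;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ga.begin(), ga.end()),
                      _["b_idx"] = IntegerVector(gb.begin(), gb.end()));
}
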