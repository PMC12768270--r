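#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps (Gotoh), allowing
// direct transitions between the two gap states: with very permissive gap
// penalties an adjacent deletion+insertion pair can outscore a poor
// substitution, so the cross transitions matter. A gap of length L costs
// gap_open + L * gap_extend. Sequences arrive as 0-based indices into the
// substitution matrix. Computed in double precision.
// [[Rcpp::export(name = ".sw_local_score")]]
double sw_local_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                      double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e300;
  std::vector<double> Mprev(m + 1, 0.0), Mcur(m + 1, 0.0);
  std::vector<double> Xprev(m + 1, NEG), Xcur(m + 1, NEG);
  std::vector<double> Yprev(m + 1, NEG), Ycur(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0.0; Xcur[0] = NEG; Ycur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double x = std::max(Mprev[j] - gap_open - gap_extend,
                          std::max(Xprev[j] - gap_extend,
                                   Yprev[j] - gap_open - gap_extend));
      double y = std::max(Mcur[j - 1] - gap_open - gap_extend,
                          std::max(Ycur[j - 1] - gap_extend,
                                   Xcur[j - 1] - gap_open - gap_extend));
      double diag = std::max(Mprev[j - 1],
                             std::max(Xprev[j - 1], Yprev[j - 1]));
      double mm = diag + sub(a[i - 1], b[j - 1]);
      if (mm < 0.0) mm = 0.0;
      Xcur[j] = x; Ycur[j] = y; Mcur[j] = mm;
      double h = std::max(mm, std::max(x, y));
      if (h > best) best = h;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  return best;
}
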