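#include <Rcpp.h>
using namespace Rcpp;

// Local alignment with affine gaps (Gotoh). Sequences arrive as 0-based
// indices into the scoring matrix. A gap of length k costs
// gap_open + k * gap_extend. Alignment start coordinates are propagated
// through the DP so the reported span needs no traceback; ties on the
// optimal score prefer the smallest query start, then subject start,
// then the smallest end coordinates.

struct Origin { int qs, ss; };

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                  double gap_open, double gap_extend) {
  const int m = q.size(), n = s.size();
  const double NEG = -1e18;
  // rolling rows
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG), Fprev(n + 1, NEG);
  std::vector<Origin> HoPrev(n + 1), HoCur(n + 1);
  std::vector<Origin> EoPrev(n + 1), EoCur(n + 1);
  std::vector<Origin> FoPrev(n + 1), FoCur(n + 1);

  double best = 0.0;
  int bqs = 1, bss = 1, bqe = 0, bse = 0;  // empty span for score 0

  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    HoCur[0] = {i + 1, 1};
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consumes subject j)
      double e_open = Hcur[j - 1] - gap_open - gap_extend;
      double e_ext  = Ecur[j - 1] - gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; EoCur[j] = HoCur[j - 1]; }
      else                 { Ecur[j] = e_ext;  EoCur[j] = EoCur[j - 1]; }
      // F: gap in subject (consumes query i)
      double f_open = Hprev[j] - gap_open - gap_extend;
      double f_ext  = Fprev[j] - gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; FoCur[j] = HoPrev[j]; }
      else                 { Fcur[j] = f_ext;  FoCur[j] = FoPrev[j]; }
      // H
      double diag = Hprev[j - 1] + mat(q[i - 1], s[j - 1]);
      Origin diag_o = (Hprev[j - 1] > 0.0) ? HoPrev[j - 1] : Origin{i, j};
      double h = 0.0; Origin ho = {i + 1, j + 1};  // "restart" origin
      if (diag >= h) { h = diag; ho = diag_o; }
      if (Ecur[j] > h) { h = Ecur[j]; ho = EoCur[j]; }
      if (Fcur[j] > h) { h = Fcur[j]; ho = FoCur[j]; }
      if (h < 0.0) { h = 0.0; ho = {i + 1, j + 1}; }
      Hcur[j] = h; HoCur[j] = ho;
      if (h > 0.0) {
        bool better = h > best;
        if (!better && h == best) {
          if (ho.qs < bqs) better = true;
          else if (ho.qs == bqs && ho.ss < bss) better = true;
          else if (ho.qs == bqs && ho.ss == bss &&
                   (i < bqe || (i == bqe && j < bse))) better = true;
        }
        if (better) { best = h; bqs = ho.qs; bss = ho.ss; bqe = i; bse = j; }
      }
    }
    std::swap(Hprev, Hcur); std::swap(HoPrev, HoCur);
    std::swap(Eprev, Ecur); std::swap(EoPrev, EoCur);
    std::swap(Fprev, Fcur); std::swap(FoPrev, FoCur);
  }
  return List::create(_["score"] = best,
                      _["q_start"] = bqs, _["q_end"] = bqe,
                      _["s_start"] = bss, _["s_end"] = bse);
}
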