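#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gap penalties (Gotoh).
// A gap of length L scores gap_open + L * gap_extend (both <= 0).
// N never counts as a match: any pair involving N scores the mismatch
// penalty. Returns 0 when no positive-scoring local alignment exists.
// [[Rcpp::export(name = ".sw_score")]]
double sw_score(std::string a, std::string b, double match,
                double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), F(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      char ca = a[i - 1], cb = b[j - 1];
      double sub = (ca == cb && ca != 'N') ? match : mismatch;
      E = std::max(E + gap_extend, Hcur[j - 1] + gap_open + gap_extend);
      F[j] = std::max(F[j] + gap_extend, Hprev[j] + gap_open + gap_extend);
      double h = std::max(0.0, std::max(Hprev[j - 1] + sub,
                                        std::max(E, F[j])));
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}
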