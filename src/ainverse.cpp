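#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm and the
// sparse inverse of the numerator relationship matrix by Henderson's rules
// with inbreeding. Pedigree must be sorted parents-before-offspring;
// sire/dam are 1-based ids, 0 = unknown.
// [[Rcpp::export]]
List cpp_ainverse(IntegerVector sire, IntegerVector dam, bool inverse = true) {
  int n = sire.size();
  NumericVector F(n);      // inbreeding coefficient
  NumericVector d(n);      // within-family (Mendelian sampling) variance
  std::vector<double> coef((size_t) n, 0.0);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    double Fs = s > 0 ? F[s - 1] : -1.0;
    double Fd = dd > 0 ? F[dd - 1] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 || dd == 0) {
      F[i] = 0.0;
      continue;
    }
    // trace ancestors of i, accumulating L coefficients; coef[] is all-zero
    // on entry and restored to all-zero by the descending sweep below
    double f = -1.0;
    coef[(size_t) i] = 1.0;
    for (int j = i; j >= 0; --j) {
      double c = coef[(size_t) j];
      if (c == 0.0) continue;
      f += c * c * d[j];
      int sj = sire[j], dj = dam[j];
      if (sj > 0) coef[(size_t) (sj - 1)] += 0.5 * c;
      if (dj > 0) coef[(size_t) (dj - 1)] += 0.5 * c;
      coef[(size_t) j] = 0.0;
    }
    F[i] = f;
  }

  if (!inverse) return List::create(_["F"] = F, _["d"] = d);

  // Henderson's rules: each animal contributes alpha = 1/d_i on a 3x3 block
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve((size_t) n * 9);
  tj.reserve((size_t) n * 9);
  tx.reserve((size_t) n * 9);
  for (int i = 0; i < n; ++i) {
    double alpha = 1.0 / d[i];
    int s = sire[i], dd = dam[i];
    ti.push_back(i + 1); tj.push_back(i + 1); tx.push_back(alpha);
    if (s > 0) {
      ti.push_back(i + 1); tj.push_back(s); tx.push_back(-0.5 * alpha);
      ti.push_back(s); tj.push_back(i + 1); tx.push_back(-0.5 * alpha);
      ti.push_back(s); tj.push_back(s); tx.push_back(0.25 * alpha);
    }
    if (dd > 0) {
      ti.push_back(i + 1); tj.push_back(dd); tx.push_back(-0.5 * alpha);
      ti.push_back(dd); tj.push_back(i + 1); tx.push_back(-0.5 * alpha);
      ti.push_back(dd); tj.push_back(dd); tx.push_back(0.25 * alpha);
    }
    if (s > 0 && dd > 0) {
      ti.push_back(s); tj.push_back(dd); tx.push_back(0.25 * alpha);
      ti.push_back(dd); tj.push_back(s); tx.push_back(0.25 * alpha);
    }
  }
  return List::create(_["F"] = F, _["d"] = d,
                      _["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
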