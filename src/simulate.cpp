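#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One meiosis under the Haldane model: Poisson(length in Morgans) crossovers
// per chromosome, placed uniformly, no interference; recurrent 0<->1 mutation
// applied per locus at rate mu. Haplotypes are raw 0/1 bytes, loci in rows.
static void make_gamete(const unsigned char* h1, const unsigned char* h2,
                        const double* pos, const int* chrStart, const int* chrEnd,
                        const double* chrLen, int nChr, double mu, int nLoci,
                        unsigned char* out) {
  for (int c = 0; c < nChr; ++c) {
    int s = chrStart[c], e = chrEnd[c];          // 0-based, inclusive; e < s => empty
    if (e < s) continue;
    double lenM = chrLen[c] / 100.0;             // cM -> Morgan
    int ncx = lenM > 0 ? (int) R::rpois(lenM) : 0;
    std::vector<double> cx((size_t) ncx);
    for (int k = 0; k < ncx; ++k) cx[(size_t) k] = R::runif(0.0, chrLen[c]);
    std::sort(cx.begin(), cx.end());
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    // copy whole segments between consecutive crossovers
    int j = s;
    for (int k = 0; k <= ncx && j <= e; ++k) {
      int stop_;
      if (k < ncx) {
        // first locus index with pos >= cx[k] (within this chromosome)
        const double* lo = std::lower_bound(pos + j, pos + e + 1, cx[(size_t) k]);
        stop_ = (int) (lo - pos);                // exclusive end of segment
      } else {
        stop_ = e + 1;
      }
      if (stop_ > j) {
        const unsigned char* src = (cur == 0) ? h1 : h2;
        std::copy(src + j, src + stop_, out + j);
        j = stop_;
      }
      cur ^= 1;
    }
  }
  if (mu > 0 && nLoci > 0) {
    int nm = (int) R::rbinom((double) nLoci, mu);
    for (int m = 0; m < nm; ++m) {
      int j = (int) (unif_rand() * nLoci);
      if (j >= nLoci) j = nLoci - 1;
      out[j] ^= 1;
    }
  }
}

// [[Rcpp::export]]
RawVector cpp_gamete(RawMatrix hap, int individual, NumericVector pos,
                     IntegerVector chrStart, IntegerVector chrEnd,
                     NumericVector chrLen, double mu) {
  int nLoci = hap.nrow();
  RawVector out(nLoci);
  const unsigned char* h1 = &hap(0, 2 * (individual - 1));
  const unsigned char* h2 = &hap(0, 2 * (individual - 1) + 1);
  make_gamete(h1, h2, pos.begin(), chrStart.begin(), chrEnd.begin(),
              chrLen.begin(), chrStart.size(), mu, nLoci, &out[0]);
  return out;
}

// Random mating at constant size for `generations` generations. Columns of
// `hap` hold two haplotypes per individual; the first nMale individuals of
// every generation (including the input) are male.
// [[Rcpp::export]]
RawMatrix cpp_random_mating(RawMatrix hap, int nMale, int nFemale,
                            NumericVector pos, IntegerVector chrStart,
                            IntegerVector chrEnd, NumericVector chrLen,
                            double mu, int generations) {
  int nLoci = hap.nrow();
  int n = nMale + nFemale;
  if (hap.ncol() != 2 * n) stop("haplotype matrix does not match population size");
  RawMatrix cur(nLoci, 2 * n), nxt(nLoci, 2 * n);
  std::copy(hap.begin(), hap.end(), cur.begin());
  for (int g = 0; g < generations; ++g) {
    for (int i = 0; i < n; ++i) {
      int sire = (int) (unif_rand() * nMale);
      if (sire >= nMale) sire = nMale - 1;
      int dam = nMale + (int) (unif_rand() * nFemale);
      if (dam >= n) dam = n - 1;
      make_gamete(&cur(0, 2 * sire), &cur(0, 2 * sire + 1), pos.begin(),
                  chrStart.begin(), chrEnd.begin(), chrLen.begin(),
                  chrStart.size(), mu, nLoci, &nxt(0, 2 * i));
      make_gamete(&cur(0, 2 * dam), &cur(0, 2 * dam + 1), pos.begin(),
                  chrStart.begin(), chrEnd.begin(), chrLen.begin(),
                  chrStart.size(), mu, nLoci, &nxt(0, 2 * i + 1));
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// Offspring from given parent indices (1-based columns into `hap` pairs).
// [[Rcpp::export]]
RawMatrix cpp_make_offspring(RawMatrix hap, IntegerVector sire, IntegerVector dam,
                             NumericVector pos, IntegerVector chrStart,
                             IntegerVector chrEnd, NumericVector chrLen,
                             double mu) {
  int nLoci = hap.nrow();
  int nOff = sire.size();
  RawMatrix out(nLoci, 2 * nOff);
  for (int i = 0; i < nOff; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    make_gamete(&hap(0, 2 * s), &hap(0, 2 * s + 1), pos.begin(),
                chrStart.begin(), chrEnd.begin(), chrLen.begin(),
                chrStart.size(), mu, nLoci, &out(0, 2 * i));
    make_gamete(&hap(0, 2 * d), &hap(0, 2 * d + 1), pos.begin(),
                chrStart.begin(), chrEnd.begin(), chrLen.begin(),
                chrStart.size(), mu, nLoci, &out(0, 2 * i + 1));
  }
  return out;
}

// Allele-1 dosage (0/1/2) per individual x locus, loci in columns.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix hap, IntegerVector loci) {
  int n = hap.ncol() / 2, m = loci.size();
  IntegerMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    int l = loci[j] - 1;
    for (int i = 0; i < n; ++i)
      out(i, j) = (int) hap(l, 2 * i) + (int) hap(l, 2 * i + 1);
  }
  return out;
}
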