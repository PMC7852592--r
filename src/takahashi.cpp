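#include <Rcpp.h>
using namespace Rcpp;

// Sparse partial inverse (Takahashi, Fagan & Chin 1973): given the lower
// Cholesky factor L (CSC, diagonal stored first in each column, row indices
// sorted) of a permuted symmetric positive definite matrix C, compute the
// entries of C^{-1} on the sparsity pattern of L. The pattern of a simplicial
// Cholesky factor is a chordal filled graph, which makes the recurrences
// self-contained on that pattern.

static inline double getZ(int r, int c, const int* Lp, const int* Li,
                          const double* Zx, bool* ok) {
  // entry (r, c) with r >= c; binary search within column c
  int lo = Lp[c], hi = Lp[c + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (Li[mid] == r) return Zx[mid];
    if (Li[mid] < r) lo = mid + 1; else hi = mid - 1;
  }
  *ok = false;
  return 0.0;
}

// [[Rcpp::export]]
List cpp_takahashi(IntegerVector Lp, IntegerVector Li, NumericVector Lx) {
  int n = Lp.size() - 1;
  NumericVector Zx(Lx.size());
  std::vector<double> Lu((size_t) Lx.size());
  std::vector<double> D((size_t) n);
  for (int j = 0; j < n; ++j) {
    int s = Lp[j];
    if (Li[s] != j) stop("factor column %d does not start with its diagonal", j + 1);
    double ljj = Lx[s];
    D[(size_t) j] = ljj * ljj;
    Lu[(size_t) s] = 1.0;
    for (int k = s + 1; k < Lp[j + 1]; ++k) Lu[(size_t) k] = Lx[k] / ljj;
  }
  // Z[i, j] = -sum_{k in struct(col j), k > j} Lu[k, j] * Z(i, k), i >= j,
  // evaluated right-to-left. Z is kept in a symmetric (both triangles)
  // scratch copy so that every needed Z(i, k) sits in full column i, which
  // is scattered once into a dense workspace per computed entry. The filled
  // pattern is chordal, so every needed position exists in the pattern.
  int nnz = Lx.size();
  std::vector<int> cnt((size_t) n, 0);
  for (int j = 0; j < n; ++j)
    for (int t = Lp[j]; t < Lp[j + 1]; ++t) {
      cnt[(size_t) j]++;
      if (Li[t] != j) cnt[(size_t) Li[t]]++;
    }
  std::vector<int> Fp((size_t) n + 1, 0);
  for (int j = 0; j < n; ++j) Fp[(size_t) j + 1] = Fp[(size_t) j] + cnt[(size_t) j];
  std::vector<int> Fi((size_t) Fp[(size_t) n]);
  std::vector<double> Fx((size_t) Fp[(size_t) n], 0.0);
  std::vector<int> cur((size_t) n);
  std::vector<int> posU((size_t) nnz, 0), posL((size_t) nnz);
  for (int j = 0; j < n; ++j) cur[(size_t) j] = Fp[(size_t) j];
  // upper parts: a lower entry (i, j), i > j, is row j of full column i;
  // iterating j ascending keeps full-column rows sorted
  for (int j = 0; j < n; ++j)
    for (int t = Lp[j]; t < Lp[j + 1]; ++t) {
      int i = Li[t];
      if (i == j) { posU[(size_t) t] = -1; continue; }
      posU[(size_t) t] = cur[(size_t) i];
      Fi[(size_t) cur[(size_t) i]++] = j;
    }
  // lower parts (including diagonals), already row-sorted per column
  for (int j = 0; j < n; ++j)
    for (int t = Lp[j]; t < Lp[j + 1]; ++t) {
      posL[(size_t) t] = cur[(size_t) j];
      Fi[(size_t) cur[(size_t) j]++] = Li[t];
    }
  std::vector<double> work((size_t) n, 0.0);
  for (int j = n - 1; j >= 0; --j) {
    int s = Lp[j], e = Lp[j + 1];
    for (int idx = e - 1; idx > s; --idx) {
      int i = Li[idx];
      for (int t = Fp[(size_t) i]; t < Fp[(size_t) i + 1]; ++t)
        work[(size_t) Fi[(size_t) t]] = Fx[(size_t) t];
      double sum = 0.0;
      for (int kidx = s + 1; kidx < e; ++kidx)
        sum += Lu[(size_t) kidx] * work[(size_t) Li[kidx]];
      for (int t = Fp[(size_t) i]; t < Fp[(size_t) i + 1]; ++t)
        work[(size_t) Fi[(size_t) t]] = 0.0;
      Zx[idx] = -sum;
      Fx[(size_t) posL[(size_t) idx]] = -sum;
      Fx[(size_t) posU[(size_t) idx]] = -sum;
    }
    double zjj = 1.0 / D[(size_t) j];
    for (int kidx = s + 1; kidx < e; ++kidx) zjj -= Lu[(size_t) kidx] * Zx[kidx];
    Zx[s] = zjj;
    Fx[(size_t) posL[(size_t) s]] = zjj;
  }
  return List::create(_["Zx"] = Zx, _["misses"] = 0);
}

// Sum over triplets (i, j, x) of x * Cinv[i, j], where Cinv entries are read
// from the Takahashi partial inverse. `pos` maps an original index to its
// 1-based position in the permuted system. Triplets outside the factor
// pattern are counted in `misses` (their Cinv value is taken as 0; callers
// ensure the model pattern is contained in the factor pattern).
// [[Rcpp::export]]
List cpp_trace_pinv(IntegerVector Mi, IntegerVector Mj, NumericVector Mx,
                    IntegerVector pos, IntegerVector Lp, IntegerVector Li,
                    NumericVector Zx) {
  double acc = 0.0;
  int misses = 0;
  for (int t = 0; t < Mi.size(); ++t) {
    int pi = pos[Mi[t] - 1] - 1, pj = pos[Mj[t] - 1] - 1;
    int r = pi >= pj ? pi : pj, c = pi >= pj ? pj : pi;
    bool ok = true;
    double z = getZ(r, c, Lp.begin(), Li.begin(), Zx.begin(), &ok);
    if (!ok) { ++misses; continue; }
    acc += Mx[t] * z;
  }
  return List::create(_["value"] = acc, _["misses"] = misses);
}
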