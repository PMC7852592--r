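#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Jacobi-preconditioned conjugate gradients for a sparse SPD system in CSC
// form (general storage, both triangles). Used for large mixed-model
// equation systems where a direct factorisation would fill in heavily.
// [[Rcpp::export]]
List cpp_pcg(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, NumericVector diag, double tol, int maxit) {
  int n = b.size();
  std::vector<double> x((size_t) n, 0.0), r(b.begin(), b.end());
  std::vector<double> z((size_t) n), p((size_t) n), ap((size_t) n);
  double nb = 0.0;
  for (int i = 0; i < n; ++i) nb += b[i] * b[i];
  nb = std::sqrt(nb);
  if (nb == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0);
  for (int i = 0; i < n; ++i) z[(size_t) i] = r[(size_t) i] / diag[i];
  p = z;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[(size_t) i] * z[(size_t) i];
  int it = 0;
  double relres = 1.0;
  while (it < maxit) {
    ++it;
    std::fill(ap.begin(), ap.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double pj = p[(size_t) j];
      if (pj == 0.0) continue;
      for (int k = Ap[j]; k < Ap[j + 1]; ++k)
        ap[(size_t) Ai[k]] += Ax[k] * pj;
    }
    double pap = 0.0;
    for (int i = 0; i < n; ++i) pap += p[(size_t) i] * ap[(size_t) i];
    double alpha = rz / pap;
    double rn = 0.0;
    for (int i = 0; i < n; ++i) {
      x[(size_t) i] += alpha * p[(size_t) i];
      r[(size_t) i] -= alpha * ap[(size_t) i];
      rn += r[(size_t) i] * r[(size_t) i];
    }
    relres = std::sqrt(rn) / nb;
    if (relres <= tol) break;
    double rznew = 0.0;
    for (int i = 0; i < n; ++i) {
      z[(size_t) i] = r[(size_t) i] / diag[i];
      rznew += r[(size_t) i] * z[(size_t) i];
    }
    double beta = rznew / rz;
    rz = rznew;
    for (int i = 0; i < n; ++i) p[(size_t) i] = z[(size_t) i] + beta * p[(size_t) i];
  }
  return List::create(_["x"] = wrap(x), _["iterations"] = it,
                      _["relres"] = relres);
}
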