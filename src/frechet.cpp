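#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two polylines given as T x C matrices
// (rows = time steps, columns = channels), Euclidean point metric.
// Eiter-Mannila dynamic program over monotone index couplings; O(T1*T2)
// memory kept to two rows.
// [[Rcpp::export(name = ".frechet_cpp")]]
double frechet_cpp(NumericMatrix P, NumericMatrix Q) {
  const int n = P.nrow(), m = Q.nrow(), C = P.ncol();
  if (n == 0 || m == 0) stop("empty sequence");
  if (Q.ncol() != C) stop("dimension mismatch");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int c = 0; c < C; ++c) {
        const double diff = P(i, c) - Q(j, c);
        d2 += diff * diff;
      }
      const double d = std::sqrt(d2);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = cur[j - 1];
      else if (j == 0) best = prev[0];
      else best = std::min(prev[j], std::min(prev[j - 1], cur[j - 1]));
      cur[j] = std::max(best, d);
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
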