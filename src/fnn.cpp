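// False-nearest-neighbour fractions by exhaustive neighbour search.
//
// For each candidate dimension m the series is delay-embedded with lag
// tau; every point's nearest neighbour (Euclidean, excluding temporal
// neighbours within the Theiler window) is located by brute force, and
// the neighbour is declared false when adding the (m+1)-th coordinate
// either stretches the pair by more than rtol relative to its m-distance
// or pushes the (m+1)-distance beyond atol attractor sizes (series
// standard deviation). O(T^2 m) per dimension; exact, no approximate
// index structure, so results are reproducible to the last bit.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".fnn_cpp")]]
NumericVector fnn_cpp(NumericVector x, int tau, int m_max, double rtol,
                      double atol, int theiler) {
  const int T = x.size();
  double mean = 0.0;
  for (int t = 0; t < T; ++t) mean += x[t];
  mean /= T;
  double ss = 0.0;
  for (int t = 0; t < T; ++t) ss += (x[t] - mean) * (x[t] - mean);
  const double sigma = std::sqrt(ss / (T - 1));

  NumericVector frac(m_max, NA_REAL);
  for (int m = 1; m <= m_max; ++m) {
    const int M = T - m * tau;  // points with a defined (m+1)-th coordinate
    if (M < 2) break;
    long total = 0, nfalse = 0;
    for (int t = 0; t < M; ++t) {
      double best = R_PosInf;
      int bi = -1;
      for (int s = 0; s < M; ++s) {
        if (std::abs(s - t) <= theiler) continue;
        double d2 = 0.0;
        for (int j = 0; j < m; ++j) {
          const double diff = x[t + j * tau] - x[s + j * tau];
          d2 += diff * diff;
        }
        if (d2 < best) { best = d2; bi = s; }
      }
      if (bi < 0) continue;
      const double Rm = std::sqrt(best);
      const double extra = std::abs(x[t + m * tau] - x[bi + m * tau]);
      bool is_false = false;
      if (Rm > 0.0) {
        if (extra / Rm > rtol) is_false = true;
      } else if (extra > 0.0) {
        is_false = true;
      }
      if (sigma > 0.0 && std::sqrt(best + extra * extra) / sigma > atol)
        is_false = true;
      ++total;
      if (is_false) ++nfalse;
    }
    frac[m - 1] = total > 0 ? (double)nfalse / (double)total : NA_REAL;
  }
  return frac;
}
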