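#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Correlation integral C(r) for one embedding dimension.
// radii2: squared radii, sorted ascending. Counts pairs with distance
// strictly below r (Heaviside convention H(0) = 0), over unordered pairs
// (i, j) with i restricted to every `stride`-th reference vector;
// stride = 1 enumerates all pairs exactly.
// [[Rcpp::export]]
NumericVector cpp_corr_curve(NumericVector x, int tau, int M,
                             NumericVector radii2, int stride = 1) {
  const int N = x.size();
  const int Np = N - (M - 1) * tau;
  const int nr = radii2.size();
  if (Np < 2) stop("epoch too short for (tau, M)");
  if (stride < 1) stop("stride must be >= 1");
  std::vector<double> cnt(nr + 1, 0.0);
  const double *r2 = REAL(radii2);
  double tot = 0.0;
  for (int i = 0; i < Np - 1; i += stride) {
    for (int j = i + 1; j < Np; ++j) {
      double d2 = 0.0;
      for (int m = 0; m < M; ++m) {
        double d = x[i + m * tau] - x[j + m * tau];
        d2 += d * d;
      }
      // first radius with d2 < r2[k]; pair contributes to all k >= p
      int p = std::upper_bound(r2, r2 + nr, d2) - r2;
      cnt[p] += 1.0;
      tot += 1.0;
    }
  }
  NumericVector C(nr);
  double acc = 0.0;
  for (int k = 0; k < nr; ++k) {
    acc += cnt[k];
    C[k] = tot > 0 ? acc / tot : NA_REAL;
  }
  return C;
}

// Correlation integrals for all embedding dimensions M = 2..M_max in a
// single pass over pairs: the squared distance at M+1 extends the one at M
// by one coordinate, so each pair is visited once and binned into the
// histogram of every M for which both vectors exist.
// radii2: (n_radii x (M_max - 1)) matrix, column m-2 holds the squared,
// ascending radius grid for embedding dimension m. Reference vectors i are
// strided as above.
// [[Rcpp::export]]
NumericMatrix cpp_corr_curves_all(NumericVector x, int tau, int M_max,
                                  NumericMatrix radii2, int stride = 1) {
  const int N = x.size();
  const int nr = radii2.nrow();
  const int nM = M_max - 1;
  if (radii2.ncol() != nM) stop("radius grid does not match M range");
  if (stride < 1) stop("stride must be >= 1");
  const int Np2 = N - tau;  // vector count at M = 2
  if (Np2 < 2) stop("epoch too short for (tau, M=2)");
  std::vector<double> cnt((size_t)nM * (nr + 1), 0.0);
  std::vector<double> tot(nM, 0.0);
  for (int i = 0; i < Np2 - 1; i += stride) {
    for (int j = i + 1; j < Np2; ++j) {
      // largest 1-based M with j (0-based) still a valid vector index
      int Mp = (N - j - 1) / tau + 1;
      if (Mp > M_max) Mp = M_max;
      double d0 = x[i] - x[j];
      double d2 = d0 * d0;
      for (int m = 2; m <= Mp; ++m) {
        double d = x[i + (m - 1) * tau] - x[j + (m - 1) * tau];
        d2 += d * d;
        const double *r2 = &radii2(0, m - 2);
        int p = std::upper_bound(r2, r2 + nr, d2) - r2;
        cnt[(size_t)(m - 2) * (nr + 1) + p] += 1.0;
        tot[m - 2] += 1.0;
      }
    }
  }
  NumericMatrix C(nr, nM);
  for (int m = 0; m < nM; ++m) {
    double acc = 0.0;
    for (int k = 0; k < nr; ++k) {
      acc += cnt[(size_t)m * (nr + 1) + k];
      C(k, m) = tot[m] > 0 ? acc / tot[m] : NA_REAL;
    }
  }
  return C;
}

// Higuchi mean curve lengths L(k), k = 1..kmax.
// L_m(k) = (1/k) * (N-1)/(n*k) * sum_{i=1}^{n} |y(m+ik) - y(m+(i-1)k)|,
// n = int((N-m)/k);  L(k) = (1/k) * sum over m = 1..k.
// [[Rcpp::export]]
NumericVector cpp_higuchi_lengths(NumericVector y, int kmax) {
  const int N = y.size();
  NumericVector L(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int valid = 0;
    for (int m = 1; m <= k; ++m) {
      int n = (N - m) / k;
      if (n < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= n; ++i)
        s += std::fabs(y[m - 1 + i * k] - y[m - 1 + (i - 1) * k]);
      Lk += (1.0 / k) * ((double)(N - 1) / ((double)n * k)) * s;
      ++valid;
    }
    L[k - 1] = valid > 0 ? Lk / k : NA_REAL;
  }
  return L;
}
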