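#include <Rcpp.h>
#include <cmath>
#include <vector>

// Discrete prolate spheroidal sequences via the symmetric tridiagonal
// commuting matrix (Slepian's trick): the DPSS of order k is the
// eigenvector belonging to the (k+1)-th largest eigenvalue of
//   T[i,i]   = ((N-1-2i)/2)^2 * cos(2*pi*w),  i = 0..N-1
//   T[i,i-1] = i*(N-i)/2,
// with w = NW/N the half-bandwidth in cycles per sample. Only the top
// `nev` eigenpairs are needed, so eigenvalues are located by Sturm-count
// bisection and eigenvectors by inverse iteration with a tridiagonal
// LU solve (partial pivoting), then Gram-Schmidt polished.

namespace {

// number of eigenvalues of (d, e) strictly below x (LDL^T Sturm count)
int sturm_count(const std::vector<double>& d, const std::vector<double>& e,
                double x) {
  const int n = static_cast<int>(d.size());
  const double tiny = 1e-300;
  int count = 0;
  double q = d[0] - x;
  if (q < 0.0) ++count;
  for (int i = 1; i < n; ++i) {
    if (q == 0.0) q = tiny;
    q = d[i] - x - e[i] * e[i] / q;
    if (q < 0.0) ++count;
  }
  return count;
}

// k-th smallest eigenvalue (k is 1-based) by bisection
double bisect_eigenvalue(const std::vector<double>& d,
                         const std::vector<double>& e,
                         int k, double lo, double hi) {
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (mid == lo || mid == hi) break;
    if (sturm_count(d, e, mid) >= k) hi = mid; else lo = mid;
    if (hi - lo <= 1e-14 * std::max(std::abs(lo), std::abs(hi)) + 1e-300)
      break;
  }
  return 0.5 * (lo + hi);
}

// solve (T - lambda I) x = b, tridiagonal LU with partial pivoting;
// b is overwritten with the solution
void tridiag_shifted_solve(const std::vector<double>& d,
                           const std::vector<double>& e,
                           double lambda, std::vector<double>& b) {
  const int n = static_cast<int>(d.size());
  std::vector<double> diag(n), sup1(n, 0.0), sup2(n, 0.0), sub(n, 0.0);
  for (int i = 0; i < n; ++i) diag[i] = d[i] - lambda;
  for (int i = 1; i < n; ++i) { sub[i] = e[i]; sup1[i - 1] = e[i]; }
  const double tiny = 1e-300;
  // forward elimination
  for (int i = 0; i < n - 1; ++i) {
    if (std::abs(sub[i + 1]) > std::abs(diag[i])) {
      std::swap(diag[i], sub[i + 1]);
      std::swap(sup1[i], diag[i + 1]);
      std::swap(sup2[i], sup1[i + 1]);  // sup2 row i was 0
      std::swap(b[i], b[i + 1]);
    }
    double piv = diag[i];
    if (piv == 0.0) piv = tiny;
    double m = sub[i + 1] / piv;
    diag[i + 1] -= m * sup1[i];
    sup1[i + 1] -= m * sup2[i];
    b[i + 1] -= m * b[i];
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double s = b[i];
    if (i + 1 < n) s -= sup1[i] * b[i + 1];
    if (i + 2 < n) s -= sup2[i] * b[i + 2];
    double piv = diag[i];
    if (piv == 0.0) piv = tiny;
    b[i] = s / piv;
  }
}

}  // namespace

// [[Rcpp::export(name = ".dpss_tapers")]]
Rcpp::NumericMatrix dpss_tapers(int N, double nw, int nev) {
  if (N < 2) Rcpp::stop("N must be at least 2");
  if (nw <= 0.0 || nw >= N / 2.0)
    Rcpp::stop("time-bandwidth product must lie in (0, N/2)");
  if (nev < 1) Rcpp::stop("nev must be at least 1");
  if (nev > N) nev = N;

  const double w = nw / static_cast<double>(N);
  const double c = std::cos(2.0 * M_PI * w);
  std::vector<double> d(N), e(N, 0.0);
  for (int i = 0; i < N; ++i) {
    double h = (N - 1.0 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 1; i < N; ++i)
    e[i] = 0.5 * static_cast<double>(i) * (static_cast<double>(N) - i);

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < N; ++i) {
    double r = (i > 0 ? std::abs(e[i]) : 0.0) +
               (i + 1 < N ? std::abs(e[i + 1]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }
  lo -= 1.0; hi += 1.0;

  Rcpp::NumericMatrix tapers(N, nev);
  std::vector<std::vector<double> > kept;
  kept.reserve(nev);

  for (int j = 0; j < nev; ++j) {
    // j-th largest eigenvalue = (N - j)-th smallest
    double lambda = bisect_eigenvalue(d, e, N - j, lo, hi);
    // inverse iteration, deterministic pseudo-random start (LCG)
    std::vector<double> v(N);
    unsigned long long s = 0x9E3779B97F4A7C15ULL ^ (static_cast<unsigned long long>(j + 1) * 0xBF58476D1CE4E5B9ULL);
    double norm = 0.0;
    for (int i = 0; i < N; ++i) {
      s = s * 6364136223846793005ULL + 1442695040888963407ULL;
      v[i] = (static_cast<double>(s >> 11) / 9007199254740992.0) - 0.5;
      norm += v[i] * v[i];
    }
    norm = std::sqrt(norm);
    for (int i = 0; i < N; ++i) v[i] /= norm;

    for (int it = 0; it < 4; ++it) {
      tridiag_shifted_solve(d, e, lambda, v);
      // orthogonalise against previously found vectors
      for (std::size_t p = 0; p < kept.size(); ++p) {
        double dot = 0.0;
        for (int i = 0; i < N; ++i) dot += v[i] * kept[p][i];
        for (int i = 0; i < N; ++i) v[i] -= dot * kept[p][i];
      }
      norm = 0.0;
      for (int i = 0; i < N; ++i) norm += v[i] * v[i];
      norm = std::sqrt(norm);
      if (norm == 0.0) Rcpp::stop("inverse iteration broke down");
      for (int i = 0; i < N; ++i) v[i] /= norm;
    }

    // polarity convention: symmetric orders (even j) have positive mean;
    // antisymmetric orders start with a positive ramp
    double stat = 0.0;
    if (j % 2 == 0) {
      for (int i = 0; i < N; ++i) stat += v[i];
    } else {
      for (int i = 0; i < N; ++i)
        stat += v[i] * (static_cast<double>(N - 1) / 2.0 - i);
    }
    if (stat < 0.0) for (int i = 0; i < N; ++i) v[i] = -v[i];

    for (int i = 0; i < N; ++i) tapers(i, j) = v[i];
    kept.push_back(v);
  }
  return tapers;
}
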