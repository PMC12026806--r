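#include <Rcpp.h>
#include <cmath>
#include <vector>

// Discrete prolate spheroidal (Slepian) sequences via the symmetric
// tridiagonal formulation (Percival & Walden 1993, ch. 8): the k-th taper is
// the eigenvector of T with diag ((N-1-2t)/2)^2 cos(2*pi*W) and off-diagonal
// t(N-t)/2, belonging to the k-th largest eigenvalue. Eigenvalues are located
// by Sturm-count bisection, eigenvectors by inverse iteration with a
// partially pivoted tridiagonal solve. O(K*N) time, exact at full N.

namespace {

// number of eigenvalues of tridiag(d, e) strictly less than x
int sturm_count(const std::vector<double>& d, const std::vector<double>& e,
                double x) {
  const int n = static_cast<int>(d.size());
  int count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    double denom = q;
    if (std::fabs(denom) < 1e-300) denom = (denom < 0 ? -1e-300 : 1e-300);
    q = d[i] - x - e[i - 1] * e[i - 1] / denom;
    if (q < 0) ++count;
  }
  return count;
}

// solve (tridiag(d, e) - shift I) x = b, partial pivoting, in place on x
void solve_shifted(const std::vector<double>& d, const std::vector<double>& e,
                   double shift, std::vector<double>& x) {
  const int n = static_cast<int>(d.size());
  std::vector<double> dl(e), dd(n), du(e), du2(n, 0.0);
  for (int i = 0; i < n; ++i) dd[i] = d[i] - shift;
  std::vector<int> piv(n, 0);
  // LU with partial pivoting (LAPACK dgttrf scheme)
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(dd[i]) >= std::fabs(dl[i])) {
      if (std::fabs(dd[i]) < 1e-300) dd[i] = 1e-300;
      double fact = dl[i] / dd[i];
      dl[i] = fact;
      dd[i + 1] -= fact * du[i];
      if (i < n - 2) du2[i] = 0.0;
    } else {
      double fact = dd[i] / dl[i];
      dd[i] = dl[i];
      dl[i] = fact;
      double tmp = du[i];
      du[i] = dd[i + 1];
      dd[i + 1] = tmp - fact * dd[i + 1];
      if (i < n - 2) {
        du2[i] = du[i + 1];
        du[i + 1] = -fact * du[i + 1];
      }
      piv[i] = 1;
    }
  }
  if (std::fabs(dd[n - 1]) < 1e-300) dd[n - 1] = 1e-300;
  // forward substitution with pivoting
  for (int i = 0; i < n - 1; ++i) {
    if (piv[i] == 0) {
      x[i + 1] -= dl[i] * x[i];
    } else {
      double tmp = x[i];
      x[i] = x[i + 1];
      x[i + 1] = tmp - dl[i] * x[i];
    }
  }
  // back substitution
  x[n - 1] /= dd[n - 1];
  if (n > 1)
    x[n - 2] = (x[n - 2] - du[n - 2] * x[n - 1]) / dd[n - 2];
  for (int i = n - 3; i >= 0; --i)
    x[i] = (x[i] - du[i] * x[i + 1] - du2[i] * x[i + 2]) / dd[i];
}

}  // namespace

// [[Rcpp::export(name = ".dpss_cpp", rng = false)]]
Rcpp::NumericMatrix dpss_cpp(int n, double nw, int k) {
  if (n < 2) Rcpp::stop("taper length must be >= 2");
  if (k < 1 || k > n) Rcpp::stop("invalid number of tapers");
  const double w = nw / n;
  const double ctpw = std::cos(2.0 * M_PI * w);

  std::vector<double> d(n), e(n - 1);
  for (int t = 0; t < n; ++t) {
    double h = (n - 1 - 2.0 * t) / 2.0;
    d[t] = h * h * ctpw;
  }
  for (int t = 1; t < n; ++t) e[t - 1] = t * (n - t) / 2.0;

  // Gershgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    if (i > 0) r += std::fabs(e[i - 1]);
    if (i < n - 1) r += std::fabs(e[i]);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }

  Rcpp::NumericMatrix tapers(n, k);
  std::vector<double> v(n);

  for (int j = 0; j < k; ++j) {
    // j-th largest eigenvalue: index (from below) n - 1 - j
    int target = n - 1 - j;
    double a = lo, b = hi;
    for (int iter = 0; iter < 120 && (b - a) > 1e-13 * std::max(1.0, std::fabs(b)); ++iter) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e, mid) <= target) a = mid; else b = mid;
    }
    double lambda = 0.5 * (a + b);

    // inverse iteration, deterministic start
    for (int i = 0; i < n; ++i) v[i] = 1.0 / std::sqrt((double)n);
    for (int it = 0; it < 4; ++it) {
      solve_shifted(d, e, lambda, v);
      double nrm = 0.0;
      for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) v[i] /= nrm;
    }
    // Gram-Schmidt against previous tapers (guards close eigenvalues)
    for (int p = 0; p < j; ++p) {
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += v[i] * tapers(i, p);
      for (int i = 0; i < n; ++i) v[i] -= dot * tapers(i, p);
    }
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) nrm += v[i] * v[i];
    nrm = std::sqrt(nrm);
    for (int i = 0; i < n; ++i) v[i] /= nrm;

    // polarity convention: symmetric tapers have positive mean, antisymmetric
    // ones a positive initial lobe
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += v[i];
    if (std::fabs(s) > 1e-8) {
      if (s < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    } else if (v[1] < v[0] || v[0] < 0) {
      if (v[0] < 0) for (int i = 0; i < n; ++i) v[i] = -v[i];
    }
    for (int i = 0; i < n; ++i) tapers(i, j) = v[i];
  }
  return tapers;
}
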