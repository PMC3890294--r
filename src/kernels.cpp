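#include <Rcpp.h>
using namespace Rcpp;

inline int sgn(double v) { return (v > 0) - (v < 0); }

// Sum over all i<j of sgn(x_i - x_j) * sgn(y_i - y_j); ties contribute 0
// (tau-a numerator). O(n^2) but branch-free inner loop; fast to n ~ 1e5.
// [[Rcpp::export]]
double kendall_pair_sum(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  double s = 0.0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i];
    long long acc = 0;
    for (R_xlen_t j = i + 1; j < n; ++j)
      acc += sgn(xi - x[j]) * sgn(yi - y[j]);
    s += (double)acc;
  }
  return s;
}

// For each candidate lower bound, continuous-MLE exponent on the tail
// x >= xmin and the KS distance between the tail's empirical CDF and the
// fitted Pareto CDF. x must be sorted ascending.
// Returns a matrix with columns: n_tail, alpha, ks.
// [[Rcpp::export]]
NumericMatrix powerlaw_ks_scan(NumericVector x_sorted, NumericVector candidates) {
  const R_xlen_t n = x_sorted.size(), m = candidates.size();
  NumericMatrix out(m, 3);
  // suffix sums of log(x)
  std::vector<double> slog(n + 1, 0.0);
  for (R_xlen_t i = n - 1; i >= 0; --i)
    slog[i] = slog[i + 1] + std::log(x_sorted[i]);
  for (R_xlen_t k = 0; k < m; ++k) {
    const double xm = candidates[k];
    // first index with x >= xm
    R_xlen_t lo = std::lower_bound(x_sorted.begin(), x_sorted.end(), xm) -
                  x_sorted.begin();
    const R_xlen_t nt = n - lo;
    if (nt < 2) { out(k, 0) = nt; out(k, 1) = NA_REAL; out(k, 2) = NA_REAL; continue; }
    const double denom = slog[lo] - (double)nt * std::log(xm);
    if (denom <= 0) { out(k, 0) = nt; out(k, 1) = NA_REAL; out(k, 2) = NA_REAL; continue; }
    const double alpha = 1.0 + (double)nt / denom;
    double d = 0.0;
    for (R_xlen_t i = 0; i < nt; ++i) {
      const double cdf = 1.0 - std::pow(xm / x_sorted[lo + i], alpha - 1.0);
      const double e_hi = (double)(i + 1) / nt, e_lo = (double)i / nt;
      d = std::max(d, std::max(std::fabs(e_hi - cdf), std::fabs(cdf - e_lo)));
    }
    out(k, 0) = (double)nt; out(k, 1) = alpha; out(k, 2) = d;
  }
  colnames(out) = CharacterVector::create("n_tail", "alpha", "ks");
  return out;
}
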