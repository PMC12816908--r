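#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Gaussian kernel CDF statistic: for gene i, sample j,
//   z_ij = mean_k Phi((x_ij - x_ik) / h_i) - 0.5
// h_i is the per-gene bandwidth (SD/4 with a small floor, computed in R).
// [[Rcpp::export(name = ".kcdf_gauss_cpp")]]
NumericMatrix kcdf_gauss_cpp(NumericMatrix x, NumericVector h) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  for (int i = 0; i < p; ++i) {
    const double hi = h[i];
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      const double xij = x(i, j);
      for (int k = 0; k < n; ++k)
        acc += R::pnorm((xij - x(i, k)) / hi, 0.0, 1.0, 1, 0);
      z(i, j) = acc / n - 0.5;
    }
  }
  return z;
}

// Discrete (Poisson) kernel CDF statistic for count data:
//   z_ij = mean_k Ppois(x_ij; lambda = x_ik + r) - 0.5, r = 0.5
// Counts repeat heavily, so the CDF is evaluated once per distinct
// value of the gene and looked up per sample.
// [[Rcpp::export(name = ".kcdf_pois_cpp")]]
NumericMatrix kcdf_pois_cpp(NumericMatrix x, double r) {
  const int p = x.nrow(), n = x.ncol();
  NumericMatrix z(p, n);
  std::vector<double> row(n);
  for (int i = 0; i < p; ++i) {
    for (int k = 0; k < n; ++k) row[k] = x(i, k);
    std::vector<double> uniq(row);
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    std::vector<double> cdf(uniq.size());
    for (size_t u = 0; u < uniq.size(); ++u) {
      double acc = 0.0;
      for (int k = 0; k < n; ++k)
        acc += R::ppois(uniq[u], row[k] + r, 1, 0);
      cdf[u] = acc / n - 0.5;
    }
    for (int j = 0; j < n; ++j) {
      size_t u = std::lower_bound(uniq.begin(), uniq.end(), x(i, j)) - uniq.begin();
      z(i, j) = cdf[u];
    }
  }
  return z;
}

// Exact two-sided permutation p-value for the Spearman correlation of two
// (average-tie) rank vectors: enumerate all n! orderings of ry, count how
// often |rho_perm| >= |rho_obs| (within a numeric epsilon). Feasible for
// n <= 10 (3.6e6 permutations).
// [[Rcpp::export(name = ".spearman_exact_p_cpp")]]
double spearman_exact_p_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  const double mx = std::accumulate(rx.begin(), rx.end(), 0.0) / n;
  const double my = std::accumulate(ry.begin(), ry.end(), 0.0) / n;
  double sxx = 0.0, syy = 0.0;
  std::vector<double> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = rx[i] - mx; cy[i] = ry[i] - my;
    sxx += cx[i] * cx[i]; syy += cy[i] * cy[i];
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  const double denom = std::sqrt(sxx * syy);
  double sxy = 0.0;
  for (int i = 0; i < n; ++i) sxy += cx[i] * cy[i];
  const double obs = std::fabs(sxy / denom) - 1e-12;

  std::vector<int> idx(n);
  std::iota(idx.begin(), idx.end(), 0);
  std::sort(idx.begin(), idx.end());
  long long total = 0, hits = 0;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += cx[i] * cy[idx[i]];
    if (std::fabs(s / denom) >= obs) ++hits;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return static_cast<double>(hits) / static_cast<double>(total);
}
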