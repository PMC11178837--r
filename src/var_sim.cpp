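#include <Rcpp.h>
using namespace Rcpp;

// Simulate a stationary VAR(p) process.
//
// coeffs: n x (n*p) matrix, horizontal concatenation [A1 A2 ... Ap].
// chol_lower: lower-triangular Cholesky factor of the innovation
//             covariance, so innovations are L %*% z with z ~ N(0, I).
// n_samples: samples returned after discarding `burn` initial samples.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix var_sim_cpp(NumericMatrix coeffs, NumericMatrix chol_lower,
                          int n_samples, int burn) {
  const int n = coeffs.nrow();
  const int p = coeffs.ncol() / n;
  const int total = n_samples + burn;
  NumericMatrix y(n, total);

  std::vector<double> z(n), e(n);
  for (int t = 0; t < total; ++t) {
    for (int i = 0; i < n; ++i) z[i] = norm_rand();
    // e = L z
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j <= i; ++j) s += chol_lower(i, j) * z[j];
      e[i] = s;
    }
    for (int i = 0; i < n; ++i) {
      double s = e[i];
      for (int k = 0; k < p; ++k) {
        int tk = t - k - 1;
        if (tk < 0) break;
        const int off = k * n;
        for (int j = 0; j < n; ++j) s += coeffs(i, off + j) * y(j, tk);
      }
      y(i, t) = s;
    }
  }

  if (burn == 0) return y;
  NumericMatrix out(n, n_samples);
  for (int t = 0; t < n_samples; ++t)
    for (int i = 0; i < n; ++i) out(i, t) = y(i, t + burn);
  return out;
}

// Accumulate the Gram matrix of [y_t, y_{t-1}, ..., y_{t-P}] over one
// contiguous segment (no regression crosses segment boundaries), plus the
// column sums of the same design.  y: n x T.  Returns list(G, s, nobs).
// [[Rcpp::export]]
List lag_gram_cpp(NumericMatrix y, int P) {
  const int n = y.nrow();
  const int T = y.ncol();
  const int m = n * (P + 1);
  NumericMatrix G(m, m);
  NumericVector s(m);
  if (T <= P) return List::create(_["G"] = G, _["s"] = s, _["nobs"] = 0);

  std::vector<double> row(m);
  for (int t = P; t < T; ++t) {
    for (int k = 0; k <= P; ++k)
      for (int j = 0; j < n; ++j) row[k * n + j] = y(j, t - k);
    for (int a = 0; a < m; ++a) {
      s[a] += row[a];
      const double ra = row[a];
      for (int b = a; b < m; ++b) G(a, b) += ra * row[b];
    }
  }
  for (int a = 0; a < m; ++a)
    for (int b = 0; b < a; ++b) G(a, b) = G(b, a);
  return List::create(_["G"] = G, _["s"] = s, _["nobs"] = T - P);
}
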