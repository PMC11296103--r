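#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping distance with a Sakoe-Chiba band constraint.
// Local cost = |x_i - y_j|; step pattern = symmetric1 (no slope weighting).
// band < 1 disables the constraint.

// [[Rcpp::export]]
double dtw_distance(NumericVector x, NumericVector y, int band = 0) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("dtw_distance: empty series");
  if (band < 1) band = std::max(n, m);
  // band must at least cover the length difference or the end is unreachable
  band = std::max(band, std::abs(n - m));
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    const int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      const double c = std::abs(x[i - 1] - y[j - 1]);
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Pairwise DTW distance matrix; rows of `series` are the individual series.

// [[Rcpp::export]]
NumericMatrix dtw_distance_matrix(NumericMatrix series, int band = 0) {
  const int n = series.nrow();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = series(i, _);
    for (int j = i + 1; j < n; ++j) {
      NumericVector yj = series(j, _);
      const double d = dtw_distance(xi, yj, band);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
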