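#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact 1-D k-means by dynamic programming over contiguous partitions of the
// sorted input.  In one dimension every optimal k-means partition is an
// interval partition of the sorted values, so the global optimum is
// computable exactly and deterministically (no Lloyd restarts).
//
// Input: xs ascending-sorted values, kmax in 1..3 (small k, so the O(k n^2)
// DP is plenty fast).  Returns, for each k = 1..kmax, the interval start
// indices (1-based, into the sorted vector), cluster means (ascending) and
// the total within-cluster sum of squares.
// [[Rcpp::export]]
List kmeans1d_dp_cpp(NumericVector xs, int kmax) {
  const int n = xs.size();
  if (n < 1) stop("empty input");
  if (kmax < 1) stop("kmax must be >= 1");
  if (kmax > n) kmax = n;

  std::vector<long double> cs(n + 1, 0.0L), css(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + xs[i];
    css[i + 1] = css[i] + (long double)xs[i] * xs[i];
  }
  // within-SS of the interval [i, j] (0-based, inclusive)
  auto cost = [&](int i, int j) -> double {
    long double s = cs[j + 1] - cs[i];
    long double ss = css[j + 1] - css[i];
    int m = j - i + 1;
    long double c = ss - s * s / m;
    return c < 0 ? 0.0 : (double)c;
  };

  // D[k][j] = minimal cost of splitting x[0..j] into k intervals
  // B[k][j] = start index of the last interval in that optimum
  std::vector<std::vector<double>> D(kmax + 1, std::vector<double>(n, R_PosInf));
  std::vector<std::vector<int>> B(kmax + 1, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) { D[1][j] = cost(0, j); B[1][j] = 0; }
  for (int k = 2; k <= kmax; ++k) {
    for (int j = k - 1; j < n; ++j) {
      for (int i = k - 1; i <= j; ++i) {
        double v = D[k - 1][i - 1] + cost(i, j);
        if (v < D[k][j]) { D[k][j] = v; B[k][j] = i; }  // first (smallest i) wins ties
      }
    }
  }

  List out(kmax);
  for (int k = 1; k <= kmax; ++k) {
    IntegerVector starts(k);
    NumericVector centers(k);
    int j = n - 1;
    for (int c = k; c >= 1; --c) {
      int i = B[c][j];
      starts[c - 1] = i + 1;
      centers[c - 1] = (double)((cs[j + 1] - cs[i]) / (j - i + 1));
      j = i - 1;
    }
    out[k - 1] = List::create(_["starts"] = starts,
                              _["centers"] = centers,
                              _["within_ss"] = D[k][n - 1]);
  }
  return out;
}
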