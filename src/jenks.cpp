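// Fisher-Jenks natural breaks: exact O(k n^2) dynamic program minimising
// total within-class sum of squared deviations over a sorted vector.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export(name = ".fisher_jenks")]]
IntegerVector fisher_jenks_cpp(const NumericVector& x_sorted, int k) {
  const int n = x_sorted.size();
  if (k < 1 || k > n) stop("k must be between 1 and length(x)");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x_sorted[i];
    cs2[i + 1] = cs2[i] + x_sorted[i] * x_sorted[i];
  }
  auto ssd = [&](int i, int j) { // SSE of x[i..j], 0-based inclusive
    const int m = j - i + 1;
    const double s = cs[j + 1] - cs[i];
    return cs2[j + 1] - cs2[i] - s * s / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // D[m][j]: min cost of splitting x[0..j] into m+1 classes
  std::vector<std::vector<double>> D(k, std::vector<double>(n, INF));
  std::vector<std::vector<int>> B(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) D[0][j] = ssd(0, j);
  for (int m = 1; m < k; ++m) {
    for (int j = m; j < n; ++j) {
      double best = INF; int arg = m;
      for (int i = m; i <= j; ++i) {
        const double c = D[m - 1][i - 1] + ssd(i, j);
        if (c < best) { best = c; arg = i; }
      }
      D[m][j] = best;
      B[m][j] = arg;
    }
  }
  // recover 1-based indices of the last element of each class
  IntegerVector ends(k);
  int j = n - 1;
  for (int m = k - 1; m >= 0; --m) {
    ends[m] = j + 1;
    if (m > 0) j = B[m][j] - 1;
  }
  return ends;
}
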