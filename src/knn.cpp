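// Brute-force k-nearest-neighbor regression kernel.  Returns, for each
// test row, the running-mean prediction at every k in ks (ks must be
// increasing); used both for prediction (single k) and for tuning the k
// grid from one distance computation.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix knn_mean_cpp(NumericMatrix train, NumericVector y,
                           NumericMatrix test, IntegerVector ks) {
  const int n = train.nrow(), p = train.ncol(), m = test.nrow();
  const int nk = ks.size();
  int kmax = 0;
  for (int j = 0; j < nk; ++j) kmax = std::max(kmax, ks[j]);
  kmax = std::min(kmax, n);

  NumericMatrix out(m, nk);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < m; ++i) {
    for (int r = 0; r < n; ++r) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        const double diff = test(i, c) - train(r, c);
        s += diff * diff;
      }
      d[r] = std::make_pair(s, r);
    }
    std::partial_sort(d.begin(), d.begin() + kmax, d.end());
    double run = 0.0;
    int j = 0;
    for (int k = 1; k <= kmax && j < nk; ++k) {
      run += y[d[k - 1].second];
      while (j < nk && std::min((int)ks[j], n) == k) {
        out(i, j) = run / k;
        ++j;
      }
    }
  }
  return out;
}
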