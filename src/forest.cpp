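// Bagged regression forest used by the learner-comparison module.
// Split search is histogram-based: each feature is discretized once into
// quantile bins, and candidate splits are evaluated from per-bin sums, so
// a node costs O(m * mtry) instead of O(m log m * mtry).  Bootstrap
// resampling and feature subsampling draw from R's RNG, so results are
// reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

const int MAX_BINS = 64;

struct Tree {
  std::vector<int> feat;      // split feature (0-based), -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<double> value;  // node mean of y
  std::vector<int> left, right;
};

struct NodeJob {
  int node;
  std::vector<int> rows;
  int depth;
};

// Sample k of n without replacement (0-based), via partial Fisher-Yates.
static std::vector<int> sample_features(int n, int k) {
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(idx[i], idx[j]);
  }
  idx.resize(k);
  return idx;
}

// Quantile bin edges per feature; bin b holds x <= edges[b], the last bin
// is unbounded.  Returns the per-row bin codes alongside the edges.
static void bin_feature(const NumericMatrix& X, int f,
                        std::vector<double>& edges,
                        std::vector<int>& codes) {
  const int n = X.nrow();
  std::vector<double> v(n);
  for (int i = 0; i < n; ++i) v[i] = X(i, f);
  std::vector<double> s(v);
  std::sort(s.begin(), s.end());
  edges.clear();
  for (int b = 1; b < MAX_BINS; ++b) {
    double q = s[(size_t)((double)b / MAX_BINS * (n - 1))];
    if (edges.empty() || q > edges.back()) edges.push_back(q);
  }
  if (!edges.empty() && edges.back() >= s[n - 1])
    edges.pop_back();  // keep the top bin non-empty
  codes.resize(n);
  for (int i = 0; i < n; ++i)
    codes[i] = (int)(std::lower_bound(edges.begin(), edges.end(), v[i]) -
                     edges.begin());
}

static Tree grow_tree(const std::vector<std::vector<int> >& codes,
                      const std::vector<std::vector<double> >& edges,
                      const NumericVector& y, const std::vector<int>& bag,
                      int mtry, int min_leaf, int min_split, int max_depth) {
  Tree tr;
  const int p = (int)codes.size();
  std::vector<NodeJob> stack;

  tr.feat.push_back(-1); tr.thr.push_back(0.0); tr.value.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  stack.push_back(NodeJob{0, bag, 0});

  double bin_sum[MAX_BINS];
  int bin_n[MAX_BINS];
  while (!stack.empty()) {
    NodeJob job = stack.back();
    stack.pop_back();
    const std::vector<int>& rows = job.rows;
    const int m = (int)rows.size();

    double sum = 0.0;
    for (int r : rows) sum += y[r];
    const double mean = sum / m;
    tr.value[job.node] = mean;
    if (m < min_split || job.depth >= max_depth) continue;

    double sse = 0.0;
    for (int r : rows) { double d = y[r] - mean; sse += d * d; }
    if (sse <= 1e-12) continue;

    int best_f = -1, best_bin = -1;
    double best_gain = 1e-12;
    std::vector<int> feats = sample_features(p, std::min(mtry, p));
    for (int f : feats) {
      const int nb = (int)edges[f].size() + 1;
      if (nb < 2) continue;
      std::fill(bin_sum, bin_sum + nb, 0.0);
      std::fill(bin_n, bin_n + nb, 0);
      const std::vector<int>& code = codes[f];
      for (int r : rows) { bin_sum[code[r]] += y[r]; ++bin_n[code[r]]; }
      double sl = 0.0; int nl = 0;
      for (int b = 0; b < nb - 1; ++b) {
        sl += bin_sum[b]; nl += bin_n[b];
        const int nr = m - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        const double sr = sum - sl;
        const double gain = sl * sl / nl + sr * sr / nr - sum * sum / m;
        if (gain > best_gain) { best_gain = gain; best_f = f; best_bin = b; }
      }
    }
    if (best_f < 0) continue;

    const std::vector<int>& code = codes[best_f];
    std::vector<int> lrows, rrows;
    for (int r : rows) {
      if (code[r] <= best_bin) lrows.push_back(r);
      else rrows.push_back(r);
    }
    if (lrows.empty() || rrows.empty()) continue;

    const int li = (int)tr.feat.size(), ri = li + 1;
    for (int c = 0; c < 2; ++c) {
      tr.feat.push_back(-1); tr.thr.push_back(0.0); tr.value.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1);
    }
    tr.feat[job.node] = best_f;
    tr.thr[job.node] = edges[best_f][best_bin];
    tr.left[job.node] = li;
    tr.right[job.node] = ri;
    stack.push_back(NodeJob{li, lrows, job.depth + 1});
    stack.push_back(NodeJob{ri, rrows, job.depth + 1});
  }
  return tr;
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int min_leaf, int min_split, int max_depth) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<double> > edges(p);
  std::vector<std::vector<int> > codes(p);
  for (int f = 0; f < p; ++f) bin_feature(X, f, edges[f], codes[f]);

  List forest(ntree);
  RNGScope scope;
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> bag(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      if (j >= n) j = n - 1;
      bag[i] = j;
    }
    Tree tr = grow_tree(codes, edges, y, bag, mtry, min_leaf, min_split,
                        max_depth);
    forest[t] = List::create(_["feat"] = wrap(tr.feat),
                             _["thr"] = wrap(tr.thr),
                             _["value"] = wrap(tr.value),
                             _["left"] = wrap(tr.left),
                             _["right"] = wrap(tr.right));
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = forest[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"], value = tr["value"];
    IntegerVector left = tr["left"], right = tr["right"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += value[node];
    }
  }
  return out / (double)ntree;
}
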