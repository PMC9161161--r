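// CART regression tree growing for the regression forest.
//
// Uses R's RNG (unif_rand) for bootstrap and feature sampling so fits are
// reproducible under set.seed() from the R side.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> var;       // 0 = leaf, else 1-based feature index
  std::vector<double> split;
  std::vector<int> left, right;
  std::vector<double> pred;
  int new_node() {
    var.push_back(0);
    split.push_back(NA_REAL);
    left.push_back(0);
    right.push_back(0);
    pred.push_back(NA_REAL);
    return static_cast<int>(var.size());  // 1-based id
  }
};

// Fisher-Yates draw of m items from 0..p-1 using R's RNG.
void sample_features(std::vector<int>& pool, int m, std::vector<int>& out) {
  int p = static_cast<int>(pool.size());
  for (int i = 0; i < m; ++i) {
    int j = i + static_cast<int>(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct BestSplit {
  int feature = -1;
  double threshold = 0.0;
  double gain = 1e-12;
};

int build(const NumericMatrix& X, const NumericVector& y,
          std::vector<int>& idx, int lo, int hi, int depth,
          int mtry, int min_node, int max_depth,
          TreeBuf& tb, std::vector<int>& fpool,
          std::vector<int>& feats,
          std::vector<std::pair<double, double> >& buf) {
  int id = tb.new_node();
  int n = hi - lo;
  double tot = 0.0, tot2 = 0.0;
  for (int i = lo; i < hi; ++i) {
    double v = y[idx[i]];
    tot += v;
    tot2 += v * v;
  }
  tb.pred[id - 1] = tot / n;
  double sse = tot2 - tot * tot / n;
  if (n <= min_node || depth >= max_depth || sse < 1e-22) return id;

  int p = X.ncol();
  sample_features(fpool, mtry, feats);
  BestSplit best;
  for (int f = 0; f < mtry; ++f) {
    int j = feats[f];
    buf.resize(n);
    for (int i = 0; i < n; ++i) {
      buf[i].first = X(idx[lo + i], j);
      buf[i].second = y[idx[lo + i]];
    }
    std::sort(buf.begin(), buf.end());
    double cs = 0.0;
    double base = tot * tot / n;
    for (int k = 1; k < n; ++k) {
      cs += buf[k - 1].second;
      if (buf[k - 1].first >= buf[k].first) continue;  // tie: no split here
      double gain = cs * cs / k + (tot - cs) * (tot - cs) / (n - k) - base;
      if (gain > best.gain) {
        best.gain = gain;
        best.feature = j;
        best.threshold = 0.5 * (buf[k - 1].first + buf[k].first);
      }
    }
  }
  if (best.feature < 0) return id;

  // partition idx[lo, hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i) {
    if (X(idx[i], best.feature) <= best.threshold) {
      std::swap(idx[i], idx[mid]);
      ++mid;
    }
  }
  if (mid == lo || mid == hi) return id;  // numeric safety

  tb.var[id - 1] = best.feature + 1;
  tb.split[id - 1] = best.threshold;
  tb.left[id - 1] = build(X, y, idx, lo, mid, depth + 1, mtry, min_node,
                          max_depth, tb, fpool, feats, buf);
  tb.right[id - 1] = build(X, y, idx, mid, hi, depth + 1, mtry, min_node,
                           max_depth, tb, fpool, feats, buf);
  (void)p;
  return id;
}

}  // namespace

// [[Rcpp::export(name = ".forest_grow")]]
List forest_grow(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                 int min_node, int max_depth) {
  int n = X.nrow(), p = X.ncol();
  RNGScope scope;
  List trees(n_trees);
  std::vector<int> idx(n), fpool(p);
  std::vector<int> feats(mtry);
  std::vector<std::pair<double, double> > buf;
  for (int j = 0; j < p; ++j) fpool[j] = j;

  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {
      int k = static_cast<int>(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    TreeBuf tb;
    build(X, y, idx, 0, n, 0, mtry, min_node, max_depth, tb, fpool, feats, buf);
    trees[t] = List::create(_["var"] = wrap(tb.var),
                            _["split"] = wrap(tb.split),
                            _["left"] = wrap(tb.left),
                            _["right"] = wrap(tb.right),
                            _["pred"] = wrap(tb.pred));
  }
  return trees;
}
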