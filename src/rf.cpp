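// Compact random forest for categorical map classification.
// CART trees, Gini impurity, bootstrap bagging, random feature subset per
// split, majority vote.  Uses R's RNG so set.seed() governs determinism.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 at leaves
  std::vector<double> thr;    // go left if x <= thr
  std::vector<int> left, right, pred;
};

int sample_int(int n) {  // 0..n-1 via R RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

void grow(Tree &t, const NumericMatrix &X, const IntegerVector &y, int K,
          std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
          int depth, int max_depth) {
  int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(0);

  int n = hi - lo;
  std::vector<int> cnt(K, 0);
  for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
  int maj = 0;
  for (int k = 1; k < K; ++k) if (cnt[k] > cnt[maj]) maj = k;
  t.pred[node] = maj;

  bool pure = cnt[maj] == n;
  if (pure || n < 2 * min_node || n < 2 || depth >= max_depth) return;

  int p = X.ncol();
  // candidate features: sample mtry without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j)
    std::swap(feats[j], feats[j + sample_int(p - j)]);

  double parent_imp = 1.0;
  for (int k = 0; k < K; ++k) {
    double f = (double)cnt[k] / n;
    parent_imp -= f * f;
  }

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<int> ord(n), lc(K);
  for (int fi = 0; fi < mtry && fi < p; ++fi) {
    int f = feats[fi];
    for (int i = 0; i < n; ++i) ord[i] = idx[lo + i];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double xa = X(a, f), xb = X(b, f);
      if (xa != xb) return xa < xb;
      return a < b;
    });
    std::fill(lc.begin(), lc.end(), 0);
    int nl = 0;
    for (int i = 0; i < n - 1; ++i) {
      lc[y[ord[i]]]++;
      nl++;
      double xl = X(ord[i], f), xr = X(ord[i + 1], f);
      if (xl == xr) continue;
      if (nl < min_node || n - nl < min_node) continue;
      double impl = 1.0, impr = 1.0;
      for (int k = 0; k < K; ++k) {
        double fl = (double)lc[k] / nl;
        double fr = (double)(cnt[k] - lc[k]) / (n - nl);
        impl -= fl * fl;
        impr -= fr * fr;
      }
      double gain = parent_imp -
        ((double)nl / n) * impl - ((double)(n - nl) / n) * impr;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = xl + (xr - xl) / 2.0;
        if (best_thr <= xl) best_thr = xl;  // guard against rounding
      }
    }
  }
  if (best_f < 0) return;

  int mid = lo;
  for (int i = lo, j = hi - 1; i <= j;) {  // partition
    if (X(idx[i], best_f) <= best_thr) { ++i; mid = i; }
    else std::swap(idx[i], idx[j--]);
  }
  if (mid == lo || mid == hi) return;  // degenerate (shouldn't happen)

  t.feature[node] = best_f;
  t.thr[node] = best_thr;
  t.left[node] = (int)t.feature.size();
  grow(t, X, y, K, idx, lo, mid, mtry, min_node, depth + 1, max_depth);
  t.right[node] = (int)t.feature.size();
  grow(t, X, y, K, idx, mid, hi, mtry, min_node, depth + 1, max_depth);
}

}  // namespace

// [[Rcpp::export(name = ".rf_train")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y0, int K, int ntree,
                  int mtry, double bag_fraction, int min_node,
                  int max_depth) {
  int n = X.nrow();
  IntegerVector y(clone(y0));
  for (int i = 0; i < n; ++i) y[i] -= 1;  // 0-based
  RNGScope rng;
  List forest(ntree);
  int nbag = std::max(1, (int)std::floor(bag_fraction * n));
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(nbag);
    for (int i = 0; i < nbag; ++i) idx[i] = sample_int(n);
    Tree t;
    grow(t, X, y, K, idx, 0, nbag, mtry, min_node, 0, max_depth);
    forest[b] = List::create(
      _["feature"] = wrap(t.feature), _["thr"] = wrap(t.thr),
      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
      _["pred"] = wrap(t.pred));
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
IntegerVector rf_predict_cpp(List forest, NumericMatrix X, int K) {
  int n = X.nrow(), ntree = forest.size();
  std::vector<std::vector<int> > trees_f(ntree), trees_l(ntree),
      trees_r(ntree), trees_p(ntree);
  std::vector<std::vector<double> > trees_t(ntree);
  for (int b = 0; b < ntree; ++b) {
    List t = forest[b];
    trees_f[b] = as<std::vector<int> >(t["feature"]);
    trees_t[b] = as<std::vector<double> >(t["thr"]);
    trees_l[b] = as<std::vector<int> >(t["left"]);
    trees_r[b] = as<std::vector<int> >(t["right"]);
    trees_p[b] = as<std::vector<int> >(t["pred"]);
  }
  IntegerVector out(n);
  std::vector<int> votes(K);
  for (int i = 0; i < n; ++i) {
    std::fill(votes.begin(), votes.end(), 0);
    for (int b = 0; b < ntree; ++b) {
      int node = 0;
      while (trees_f[b][node] >= 0) {
        node = X(i, trees_f[b][node]) <= trees_t[b][node]
                   ? trees_l[b][node] : trees_r[b][node];
      }
      votes[trees_p[b][node]]++;
    }
    int best = 0;
    for (int k = 1; k < K; ++k) if (votes[k] > votes[best]) best = k;
    out[i] = best + 1;  // ties -> smallest class index
  }
  return out;
}
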