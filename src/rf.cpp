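// Random forest classifier: CART trees on bootstrap samples, Gini impurity,
// mtry random candidate features per split, probability estimates as the
// average of per-tree leaf class proportions. Written against R's RNG so
// set.seed() on the R side makes fits reproducible.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<std::vector<double>> prob;
};

int rand_int(int n) {  // uniform on 0..n-1 via R's RNG
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double gini(const std::vector<double>& counts, double total) {
  if (total <= 0) return 0.0;
  double s = 0.0;
  for (double c : counts) s += (c / total) * (c / total);
  return 1.0 - s;
}

int grow(const NumericMatrix& X, const IntegerVector& y, int K,
         std::vector<int>& idx, int lo, int hi, int depth,
         int mtry, int min_node, int max_depth, TreeBuf& tb) {
  int n = hi - lo;
  std::vector<double> counts(K, 0.0);
  for (int i = lo; i < hi; ++i) counts[y[idx[i]]] += 1.0;
  bool pure = false;
  for (int k = 0; k < K; ++k) if (counts[k] == (double)n) pure = true;

  int node = (int)tb.feat.size();
  tb.feat.push_back(-1);
  tb.thr.push_back(0.0);
  tb.left.push_back(-1);
  tb.right.push_back(-1);
  std::vector<double> pr(K);
  for (int k = 0; k < K; ++k) pr[k] = counts[k] / std::max(n, 1);
  tb.prob.push_back(pr);

  if (pure || n < 2 * min_node || depth >= max_depth) return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry && j < p; ++j)
    std::swap(feats[j], feats[j + rand_int(p - j)]);

  double parent_imp = gini(counts, n);
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int jj = 0; jj < mtry && jj < p; ++jj) {
    int j = feats[jj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    std::vector<double> lc(K, 0.0);
    for (int i = 0; i < n - 1; ++i) {
      lc[y[ord[i]]] += 1.0;
      double v = X(ord[i], j), vn = X(ord[i + 1], j);
      if (vn <= v) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      std::vector<double> rc(K);
      for (int k = 0; k < K; ++k) rc[k] = counts[k] - lc[k];
      double child = (nl * gini(lc, nl) + nr * gini(rc, nr)) / n;
      double gain = parent_imp - child;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (v + vn);
      }
    }
  }
  if (best_feat < 0) return node;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  tb.feat[node] = best_feat;
  tb.thr[node] = best_thr;
  int l = grow(X, y, K, idx, lo, mid, depth + 1, mtry, min_node, max_depth, tb);
  tb.left[node] = l;
  int r = grow(X, y, K, idx, mid, hi, depth + 1, mtry, min_node, max_depth, tb);
  tb.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int K, int num_trees,
                int mtry, int min_node, int max_depth) {
  int n = X.nrow();
  List forest(num_trees);
  for (int t = 0; t < num_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap
    TreeBuf tb;
    grow(X, y, K, idx, 0, n, 0, mtry, min_node, max_depth, tb);
    int m = (int)tb.feat.size();
    NumericMatrix nodes(m, 4 + K);
    for (int i = 0; i < m; ++i) {
      nodes(i, 0) = tb.feat[i];
      nodes(i, 1) = tb.thr[i];
      nodes(i, 2) = tb.left[i];
      nodes(i, 3) = tb.right[i];
      for (int k = 0; k < K; ++k) nodes(i, 4 + k) = tb.prob[i][k];
    }
    forest[t] = nodes;
  }
  return forest;
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List forest, NumericMatrix X, int K) {
  int n = X.nrow(), T = forest.size();
  NumericMatrix out(n, K);
  for (int t = 0; t < T; ++t) {
    NumericMatrix nodes = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (nodes(node, 0) >= 0) {
        int j = (int)nodes(node, 0);
        node = X(i, j) <= nodes(node, 1) ? (int)nodes(node, 2)
                                         : (int)nodes(node, 3);
      }
      for (int k = 0; k < K; ++k) out(i, k) += nodes(node, 4 + k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) out(i, k) /= T;
  return out;
}
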