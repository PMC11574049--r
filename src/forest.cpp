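// Bagged CART ensemble for pixel classification (Gini splits, random
// feature subsets, bootstrap resampling). Deterministic for a fixed seed:
// all randomness comes from per-tree std::mt19937 streams, independent of
// R's RNG.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeArrays {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold; // go left if x <= threshold
  std::vector<int> left, right;
  std::vector<double> prob;      // positive fraction at the node
};

double gini_pair(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

int grow(TreeArrays &t, const NumericMatrix &X, const IntegerVector &y,
         std::vector<int> &idx, int lo, int hi, int depth, int max_depth,
         int min_node, int mtry, std::mt19937 &rng) {
  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  int node = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.prob.push_back((double)n1 / (double)n);
  if (depth >= max_depth || n < 2 * min_node || n1 == 0 || n1 == n)
    return node;

  int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates to draw mtry distinct features
  for (int j = 0; j < mtry && j < p; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  double best_score = -1.0, best_thr = 0.0;
  int best_feat = -1;
  double parent = (double)n * gini_pair((double)n1, (double)n);
  std::vector<int> ord(n);
  for (int fj = 0; fj < mtry && fj < p; ++fj) {
    int f = feats[fj];
    for (int i = 0; i < n; ++i) ord[i] = idx[lo + i];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double nl = 0.0, nl1 = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      nl += 1.0;
      nl1 += y[ord[i]];
      double v = X(ord[i], f), vn = X(ord[i + 1], f);
      if (v == vn) continue;
      if (nl < min_node || (n - nl) < min_node) continue;
      double impur = nl * gini_pair(nl1, nl) +
                     (n - nl) * gini_pair(n1 - nl1, n - nl);
      double score = parent - impur;
      if (score > best_score + 1e-12) {
        best_score = score;
        best_feat = f;
        best_thr = 0.5 * (v + vn);
      }
    }
  }
  if (best_feat < 0 || best_score <= 1e-12) return node;

  // in-place partition of idx[lo, hi)
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  t.feature[node] = best_feat;
  t.threshold[node] = best_thr;
  int l = grow(t, X, y, idx, lo, mid, depth + 1, max_depth, min_node,
               mtry, rng);
  int r = grow(t, X, y, idx, mid, hi, depth + 1, max_depth, min_node,
               mtry, rng);
  t.left[node] = l;
  t.right[node] = r;
  return node;
}

} // namespace

// [[Rcpp::export]]
List rf_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
            int min_node, int max_depth, int seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y sizes differ");
  List trees(n_trees);
  for (int tr = 0; tr < n_trees; ++tr) {
    std::mt19937 rng((unsigned)(seed + 1000003 * (tr + 1)));
    std::uniform_int_distribution<int> boot(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeArrays t;
    grow(t, X, y, idx, 0, n, 0, max_depth, min_node, mtry, rng);
    trees[tr] = List::create(
        _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
        _["threshold"] = NumericVector(t.threshold.begin(),
                                       t.threshold.end()),
        _["left"] = IntegerVector(t.left.begin(), t.left.end()),
        _["right"] = IntegerVector(t.right.begin(), t.right.end()),
        _["prob"] = NumericVector(t.prob.begin(), t.prob.end()));
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), n_trees = trees.size();
  NumericVector votes(n);
  for (int tr = 0; tr < n_trees; ++tr) {
    List t = trees[tr];
    IntegerVector feature = t["feature"];
    NumericVector threshold = t["threshold"];
    IntegerVector left = t["left"], right = t["right"];
    NumericVector prob = t["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      }
      if (prob[node] >= 0.5) votes[i] += 1.0; // each tree votes its leaf
    }
  }
  return votes / (double)n_trees;
}
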