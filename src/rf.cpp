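// Bagged CART regression forest with impurity-based importance.  Trees are
// grown to purity (variance-reduction splits, unlimited depth, minimum split
// size 5, minimum leaf size 1) on bootstrap samples, with mtry features
// considered per split.  A dedicated Mersenne Twister makes the forest
// deterministic for a given seed independently of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node { int feature; double threshold; int left, right; double value; };

static void grow_tree(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& idx, int lo, int hi,
                      std::vector<Node>& nodes, int node_id, int mtry,
                      int min_split, std::mt19937& rng,
                      std::vector<double>& importance, int n_root) {
  const int m = hi - lo;
  double sum = 0, ss = 0;
  for (int k = lo; k < hi; ++k) { sum += y[idx[k]]; ss += y[idx[k]] * y[idx[k]]; }
  const double mean = sum / m;
  nodes[node_id].value = mean;
  nodes[node_id].feature = -1;
  const double sse_parent = ss - sum * sum / m;
  if (m < min_split || sse_parent <= 1e-12) return;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  for (int j = 0; j < mtry; ++j) {     // partial Fisher-Yates
    std::uniform_int_distribution<int> U(j, p - 1);
    std::swap(feats[j], feats[U(rng)]);
  }

  int best_feat = -1; double best_thr = 0, best_gain = 1e-12;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int fj = 0; fj < mtry; ++fj) {
    const int f = feats[fj];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lsum = 0, lss = 0;
    for (int k = 0; k < m - 1; ++k) {
      const double yi = y[ord[k]];
      lsum += yi; lss += yi * yi;
      if (X(ord[k], f) == X(ord[k + 1], f)) continue;  // no split inside ties
      const int nl = k + 1, nr = m - nl;
      const double rsum = sum - lsum, rss = ss - lss;
      const double sse = (lss - lsum * lsum / nl) + (rss - rsum * rsum / nr);
      const double gain = sse_parent - sse;
      if (gain > best_gain) {
        best_gain = gain; best_feat = f;
        best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
      }
    }
  }
  if (best_feat < 0) return;

  // partition idx[lo,hi) in place
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_feat) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return;

  importance[best_feat] += best_gain / n_root;
  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  nodes.push_back(Node{-1, 0, -1, -1, 0});
  nodes.push_back(Node{-1, 0, -1, -1, 0});
  const int lid = nodes.size() - 2, rid = nodes.size() - 1;
  nodes[node_id].left = lid;
  nodes[node_id].right = rid;
  grow_tree(X, y, idx, lo, mid, nodes, lid, mtry, min_split, rng,
            importance, n_root);
  grow_tree(X, y, idx, mid, hi, nodes, rid, mtry, min_split, rng,
            importance, n_root);
}

// [[Rcpp::export]]
List build_forest_cpp(const NumericMatrix& X, const NumericVector& y,
                      int n_trees, int mtry, int min_split, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::uniform_int_distribution<int> boot(0, n - 1);
  List trees(n_trees);
  std::vector<double> importance(X.ncol(), 0.0);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    std::vector<Node> nodes;
    nodes.push_back(Node{-1, 0, -1, -1, 0});
    grow_tree(X, y, idx, 0, n, nodes, 0, mtry, min_split, rng, importance, n);
    NumericMatrix tm(nodes.size(), 5);
    for (size_t k = 0; k < nodes.size(); ++k) {
      tm(k, 0) = nodes[k].feature; tm(k, 1) = nodes[k].threshold;
      tm(k, 2) = nodes[k].left; tm(k, 3) = nodes[k].right;
      tm(k, 4) = nodes[k].value;
    }
    trees[t] = tm;
  }
  NumericVector imp(importance.begin(), importance.end());
  for (int j = 0; j < imp.size(); ++j) imp[j] /= n_trees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(const List& trees, const NumericMatrix& X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        const int f = static_cast<int>(tm(node, 0));
        node = (X(i, f) <= tm(node, 1)) ? static_cast<int>(tm(node, 2))
                                        : static_cast<int>(tm(node, 3));
      }
      out[i] += tm(node, 4);
    }
  }
  return out / static_cast<double>(T);
}
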