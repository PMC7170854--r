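// Classification trees and bagged random forest for binary labels.
// CART with Gini impurity; per-node feature subsampling (mtry); bootstrap
// bagging. All randomness is drawn from R's RNG so results are reproducible
// under set.seed(). Trees are returned as plain numeric matrices
// (feature, threshold, left, right, prob) so fitted models are ordinary,
// serializable R objects.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // node indices; -1 for leaf
  double prob;      // positive-class fraction of training rows in node
};

static int r_unif_int(int n) {
  // uniform integer in [0, n) from R's RNG
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

static void grow_tree(const NumericMatrix& X, const IntegerVector& y,
                      std::vector<int>& rows, int mtry, int min_node,
                      int max_depth, std::vector<Node>& nodes) {
  const int p = X.ncol();
  struct Task { int node; std::vector<int> rows; int depth; };
  std::vector<Task> stack;
  nodes.clear();
  nodes.push_back(Node());
  stack.push_back(Task{0, rows, 0});
  std::vector<int> feats(p);

  while (!stack.empty()) {
    Task t = std::move(stack.back());
    stack.pop_back();
    Node& nd = nodes[t.node];
    const std::vector<int>& r = t.rows;
    int n = (int)r.size();
    int pos = 0;
    for (int i = 0; i < n; ++i) pos += y[r[i]];
    nd.prob = (double)pos / n;
    nd.feature = -1; nd.left = nd.right = -1; nd.threshold = 0.0;
    if (pos == 0 || pos == n || n < 2 * min_node ||
        (max_depth > 0 && t.depth >= max_depth)) {
      continue; // leaf
    }

    // sample mtry candidate features without replacement (partial shuffle)
    for (int i = 0; i < p; ++i) feats[i] = i;
    int ncand = std::min(mtry, p);
    for (int i = 0; i < ncand; ++i) {
      int j = i + r_unif_int(p - i);
      std::swap(feats[i], feats[j]);
    }

    double parent_gini = 1.0 - ((double)pos / n) * ((double)pos / n)
      - ((double)(n - pos) / n) * ((double)(n - pos) / n);
    double best_gain = 1e-12;
    int best_f = -1; double best_thr = 0.0;

    std::vector<std::pair<double,int> > vals(n);
    for (int fi = 0; fi < ncand; ++fi) {
      int f = feats[fi];
      for (int i = 0; i < n; ++i) vals[i] = std::make_pair(X(r[i], f), y[r[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int ln = i + 1, rn = n - ln;
        if (ln < min_node || rn < min_node) continue;
        int rpos = pos - lpos;
        double gl = 1.0 - ((double)lpos / ln) * ((double)lpos / ln)
          - ((double)(ln - lpos) / ln) * ((double)(ln - lpos) / ln);
        double gr = 1.0 - ((double)rpos / rn) * ((double)rpos / rn)
          - ((double)(rn - rpos) / rn) * ((double)(rn - rpos) / rn);
        double gain = parent_gini - ((double)ln / n) * gl - ((double)rn / n) * gr;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) continue; // no useful split among candidates

    std::vector<int> lrows, rrows;
    lrows.reserve(n); rrows.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(r[i], best_f) <= best_thr) lrows.push_back(r[i]);
      else rrows.push_back(r[i]);
    }
    if (lrows.empty() || rrows.empty()) continue;

    int li = (int)nodes.size(); nodes.push_back(Node());
    int ri = (int)nodes.size(); nodes.push_back(Node());
    nodes[t.node].feature = best_f;
    nodes[t.node].threshold = best_thr;
    nodes[t.node].left = li;
    nodes[t.node].right = ri;
    stack.push_back(Task{li, std::move(lrows), t.depth + 1});
    stack.push_back(Task{ri, std::move(rrows), t.depth + 1});
  }
}

static NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix M((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    M(i, 0) = nodes[i].feature;
    M(i, 1) = nodes[i].threshold;
    M(i, 2) = nodes[i].left;
    M(i, 3) = nodes[i].right;
    M(i, 4) = nodes[i].prob;
  }
  colnames(M) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "prob");
  return M;
}

// [[Rcpp::export]]
List cpp_forest_train(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                      int min_node, int max_depth, bool bootstrap) {
  RNGScope scope;
  const int n = X.nrow();
  List trees(ntree);
  std::vector<Node> nodes;
  std::vector<int> rows(n);
  for (int t = 0; t < ntree; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = r_unif_int(n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    grow_tree(X, y, rows, mtry, min_node, max_depth, nodes);
    trees[t] = pack_tree(nodes);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix M = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while ((int)M(node, 0) >= 0) {
        int f = (int)M(node, 0);
        node = (X(i, f) <= M(node, 1)) ? (int)M(node, 2) : (int)M(node, 3);
      }
      out[i] += M(node, 4);
    }
  }
  return out / (double)trees.size();
}
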