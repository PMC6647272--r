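// Compact classification random forest for genotype dosages (classes 0/1/2,
// predictors are dosages too, so each feature admits only the two split
// points <=0 and <=1). Bootstrap sampling, Gini impurity, feature subsampling
// at every node. Used by the iterative (MissForest-style) imputation path.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;       // -1: leaf
  double threshold = 0.5; // split: x <= threshold goes left
  int left = -1, right = -1;
  int pred = 0;
};

static double gini(const std::array<int, 3>& c) {
  int n = c[0] + c[1] + c[2];
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int k = 0; k < 3; ++k) {
    double p = static_cast<double>(c[k]) / n;
    g -= p * p;
  }
  return g;
}

static int majority(const std::array<int, 3>& c) {
  int best = 0;
  for (int k = 1; k < 3; ++k) if (c[k] > c[best]) best = k;
  return best;
}

static void build(std::vector<Node>& tree, int node_id,
                  const NumericMatrix& X, const IntegerVector& y,
                  std::vector<int>& rows, int depth, int max_depth,
                  int min_node, int mtry) {
  std::array<int, 3> cnt{0, 0, 0};
  for (int r : rows) cnt[y[r]]++;
  Node& node = tree[node_id];
  node.pred = majority(cnt);
  double g0 = gini(cnt);
  if (depth >= max_depth || static_cast<int>(rows.size()) < min_node || g0 <= 0)
    return;

  const int p = X.ncol();
  int best_f = -1; double best_t = 0.5, best_gain = 1e-12;
  for (int m = 0; m < mtry; ++m) {
    int f = static_cast<int>(unif_rand() * p);
    if (f >= p) f = p - 1;
    for (double t : {0.5, 1.5}) {
      std::array<int, 3> lc{0, 0, 0}, rc{0, 0, 0};
      for (int r : rows) {
        if (X(r, f) <= t) lc[y[r]]++; else rc[y[r]]++;
      }
      int nl = lc[0] + lc[1] + lc[2], nr = rc[0] + rc[1] + rc[2];
      if (nl == 0 || nr == 0) continue;
      double gain = g0 - (nl * gini(lc) + nr * gini(rc)) / rows.size();
      if (gain > best_gain) { best_gain = gain; best_f = f; best_t = t; }
    }
  }
  if (best_f < 0) return;

  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, best_f) <= best_t) lrows.push_back(r); else rrows.push_back(r);
  }
  int li = tree.size(); tree.push_back(Node());
  int ri = tree.size(); tree.push_back(Node());
  tree[node_id].feature = best_f;
  tree[node_id].threshold = best_t;
  tree[node_id].left = li;
  tree[node_id].right = ri;
  build(tree, li, X, y, lrows, depth + 1, max_depth, min_node, mtry);
  build(tree, ri, X, y, rrows, depth + 1, max_depth, min_node, mtry);
}

static int predict_tree(const std::vector<Node>& tree, const NumericMatrix& X,
                        int row) {
  int id = 0;
  while (tree[id].feature >= 0) {
    id = (X(row, tree[id].feature) <= tree[id].threshold) ? tree[id].left
                                                          : tree[id].right;
  }
  return tree[id].pred;
}

// [[Rcpp::export]]
IntegerVector rf_classify(NumericMatrix X_train, IntegerVector y_train,
                          NumericMatrix X_test, int n_tree, int seed) {
  (void)seed; // RNG comes from R's stream (set upstream)
  const int n = X_train.nrow();
  const int n_test = X_test.nrow();
  const int p = X_train.ncol();
  int mtry = std::max(1, static_cast<int>(std::sqrt(static_cast<double>(p))));
  std::vector<std::array<int, 3>> votes(n_test, std::array<int, 3>{0, 0, 0});

  for (int t = 0; t < n_tree; ++t) {
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      int r = static_cast<int>(unif_rand() * n);
      if (r >= n) r = n - 1;
      rows[i] = r;
    }
    std::vector<Node> tree;
    tree.push_back(Node());
    build(tree, 0, X_train, y_train, rows, 0, /*max_depth=*/6,
          /*min_node=*/2, mtry);
    for (int i = 0; i < n_test; ++i) votes[i][predict_tree(tree, X_test, i)]++;
  }
  IntegerVector out(n_test);
  for (int i = 0; i < n_test; ++i) {
    auto& v = votes[i];
    int best = 0;
    for (int k = 1; k < 3; ++k) if (v[k] > v[best]) best = k;
    out[i] = best;
  }
  return out;
}
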