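// Randomized-tree ensemble (bagged CART, Gini splits, random feature
// subsets) and an exact interventional Shapley evaluator over the fitted
// trees.  Kept in C++ because stability selection evaluates the explainer
// for every (training sample, background row, tree) triple.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;       // 0-based split feature, -1 for leaf
  double threshold;  // x[feature] <= threshold -> left
  int left, right;   // 0-based node indices, -1 for leaf
  double value;      // positive-class fraction in the node
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;
};

double gini_impurity(double n_pos, double n_tot) {
  if (n_tot <= 0.0) return 0.0;
  double p = n_pos / n_tot;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

// Best Gini split over `mtry` features drawn without replacement.
SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx, int mtry,
                       std::mt19937& rng) {
  const int n = static_cast<int>(idx.size());
  const int p = X.ncol();
  double n_pos = 0.0;
  for (int i : idx) n_pos += y[i];
  const double parent = gini_impurity(n_pos, n);

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  // partial Fisher-Yates: first mtry entries are the candidate features
  for (int j = 0; j < mtry; ++j) {
    std::uniform_int_distribution<int> pick(j, p - 1);
    std::swap(feats[j], feats[pick(rng)]);
  }

  SplitResult best;
  std::vector<std::pair<double, int>> vals(n);
  for (int t = 0; t < mtry; ++t) {
    const int f = feats[t];
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    double left_pos = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      left_pos += vals[i].second;
      if (vals[i + 1].first <= vals[i].first) continue;  // not a boundary
      const double nl = i + 1, nr = n - nl;
      const double child = (nl / n) * gini_impurity(left_pos, nl) +
                           (nr / n) * gini_impurity(n_pos - left_pos, nr);
      const double gain = parent - child;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return best;
}

int grow(const NumericMatrix& X, const IntegerVector& y,
         const std::vector<int>& idx, int depth, int max_depth,
         int min_split, int mtry, std::mt19937& rng,
         std::vector<Node>& nodes) {
  const int n = static_cast<int>(idx.size());
  double n_pos = 0.0;
  for (int i : idx) n_pos += y[i];

  Node leaf{-1, 0.0, -1, -1, n_pos / n};
  const bool pure = (n_pos == 0.0 || n_pos == n);
  if (depth >= max_depth || n < min_split || pure) {
    nodes.push_back(leaf);
    return static_cast<int>(nodes.size()) - 1;
  }
  SplitResult s = best_split(X, y, idx, mtry, rng);
  if (s.feature < 0) {
    nodes.push_back(leaf);
    return static_cast<int>(nodes.size()) - 1;
  }
  std::vector<int> left_idx, right_idx;
  for (int i : idx) {
    if (X(i, s.feature) <= s.threshold)
      left_idx.push_back(i);
    else
      right_idx.push_back(i);
  }
  if (left_idx.empty() || right_idx.empty()) {
    nodes.push_back(leaf);
    return static_cast<int>(nodes.size()) - 1;
  }
  const int me = static_cast<int>(nodes.size());
  nodes.push_back(Node{s.feature, s.threshold, -1, -1, n_pos / n});
  const int l = grow(X, y, left_idx, depth + 1, max_depth, min_split, mtry,
                     rng, nodes);
  const int r = grow(X, y, right_idx, depth + 1, max_depth, min_split, mtry,
                     rng, nodes);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

NumericMatrix pack(const std::vector<Node>& nodes) {
  NumericMatrix m(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    m(i, 0) = nodes[i].feature;
    m(i, 1) = nodes[i].threshold;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  colnames(m) = CharacterVector::create("feature", "threshold", "left",
                                        "right", "value");
  return m;
}

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X,
                    int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = static_cast<int>(tree(node, 0));
    node = (X(row, f) <= tree(node, 1)) ? static_cast<int>(tree(node, 2))
                                        : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

// Recursive walk for the interventional Shapley decomposition of a single
// tree against a single background row z.  `state` holds, for each feature
// on the current path, whether reaching the leaf requires that feature to
// be taken from the instance (IN) or from the background (OUT).
constexpr int S_NONE = 0, S_IN = 1, S_OUT = 2;

void shap_walk(const NumericMatrix& tree, int node, const NumericMatrix& X,
               int xi, const NumericMatrix& Z, int zi,
               std::vector<int>& state, std::vector<int>& constrained,
               int a, int b, const std::vector<double>& fact, double w,
               double* phi_row, double& phi0) {
  if (tree(node, 0) < 0) {  // leaf
    const double v = tree(node, 4) * w;
    if (a == 0) phi0 += v;
    if (a + b == 0) return;
    const double w_in = (a > 0) ? fact[a - 1] * fact[b] / fact[a + b] : 0.0;
    const double w_out = (b > 0) ? fact[a] * fact[b - 1] / fact[a + b] : 0.0;
    for (int f : constrained) {
      if (state[f] == S_IN)
        phi_row[f] += v * w_in;
      else
        phi_row[f] -= v * w_out;
    }
    return;
  }
  const int f = static_cast<int>(tree(node, 0));
  const double thr = tree(node, 1);
  const int kids[2] = {static_cast<int>(tree(node, 2)),
                       static_cast<int>(tree(node, 3))};
  const bool x_left = X(xi, f) <= thr;
  const bool z_left = Z(zi, f) <= thr;
  for (int side = 0; side < 2; ++side) {
    const bool x_here = (side == 0) ? x_left : !x_left;
    const bool z_here = (side == 0) ? z_left : !z_left;
    if (!x_here && !z_here) continue;  // unreachable under any coalition
    int need = S_NONE;
    if (x_here && !z_here) need = S_IN;
    if (!x_here && z_here) need = S_OUT;
    if (need == S_NONE || state[f] == need) {
      // unconstrained, or the same constraint is already on the path
      shap_walk(tree, kids[side], X, xi, Z, zi, state, constrained, a, b,
                fact, w, phi_row, phi0);
    } else if (state[f] == S_NONE) {
      state[f] = need;
      constrained.push_back(f);
      shap_walk(tree, kids[side], X, xi, Z, zi, state, constrained,
                a + (need == S_IN), b + (need == S_OUT), fact, w, phi_row,
                phi0);
      constrained.pop_back();
      state[f] = S_NONE;
    }
    // conflicting constraint on the same feature: branch unreachable
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int max_depth, int min_split, int seed) {
  const int n = X.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    // one independent, reproducible stream per tree
    std::mt19937 rng(static_cast<uint32_t>(seed) * 2654435761u +
                     static_cast<uint32_t>(t) + 1u);
    std::vector<int> idx(n);
    std::uniform_int_distribution<int> boot(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    std::vector<Node> nodes;
    nodes.reserve(64);
    grow(X, y, idx, 0, max_depth, min_split, mtry, rng, nodes);
    trees[t] = pack(nodes);
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

// Exact Shapley values of the ensemble's positive-class probability under
// the marginal (interventional) coalition value, averaged over the rows of
// the background matrix Z.
// [[Rcpp::export(name = ".cpp_tree_shap")]]
List cpp_tree_shap(List trees, NumericMatrix X, NumericMatrix Z) {
  const int n = X.nrow(), p = X.ncol(), nb = Z.nrow(), T = trees.size();
  std::vector<double> fact(2048);
  fact[0] = 1.0;
  for (size_t k = 1; k < fact.size(); ++k) fact[k] = fact[k - 1] * k;

  std::vector<double> phi_acc(static_cast<size_t>(n) * p, 0.0);
  double phi0 = 0.0;
  const double w = 1.0 / (static_cast<double>(T) * nb);
  std::vector<int> state(p, S_NONE);
  std::vector<int> constrained;
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = trees[t];
    for (int zi = 0; zi < nb; ++zi) {
      for (int xi = 0; xi < n; ++xi) {
        double row_phi0 = 0.0;
        shap_walk(tree, 0, X, xi, Z, zi, state, constrained, 0, 0, fact, w,
                  phi_acc.data() + static_cast<size_t>(xi) * p, row_phi0);
        if (xi == 0) phi0 += row_phi0;  // phi0 is instance-independent
      }
    }
  }
  NumericMatrix phi(n, p);
  for (int i = 0; i < n; ++i)
    for (int f = 0; f < p; ++f) phi(i, f) = phi_acc[static_cast<size_t>(i) * p + f];
  return List::create(_["phi"] = phi, _["phi0"] = phi0);
}
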