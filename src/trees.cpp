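// Regression tree ensembles (bagged forests and gradient boosting) with
// impurity-decrease importances and exact tree-path Shapley attributions.
// Self-contained because no tree-ensemble package ships with the target
// image. Trees are exchanged with R as numeric matrices, one row per node:
//   col 0 feature (-1 = leaf), 1 threshold, 2 left, 3 right, 4 value, 5 cover
// An ensemble predicts init + tree_weight * sum_t tree_t(x), which covers
// both averaging forests (init = 0, weight = 1/T) and boosting (init = mean,
// weight = learning rate, values already per-tree raw means of residuals).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value, cover;
  int n_nodes() const { return (int)feature.size(); }
};

Tree tree_from_matrix(const NumericMatrix& m) {
  Tree t;
  int n = m.nrow();
  t.feature.resize(n); t.left.resize(n); t.right.resize(n);
  t.threshold.resize(n); t.value.resize(n); t.cover.resize(n);
  for (int i = 0; i < n; ++i) {
    t.feature[i] = (int)m(i, 0);
    t.threshold[i] = m(i, 1);
    t.left[i] = (int)m(i, 2);
    t.right[i] = (int)m(i, 3);
    t.value[i] = m(i, 4);
    t.cover[i] = m(i, 5);
  }
  return t;
}

NumericMatrix tree_to_matrix(const Tree& t) {
  NumericMatrix m(t.n_nodes(), 6);
  for (int i = 0; i < t.n_nodes(); ++i) {
    m(i, 0) = t.feature[i]; m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];   m(i, 5) = t.cover[i];
  }
  return m;
}

double predict_tree(const Tree& t, const double* x) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (x[t.feature[node]] <= t.threshold[node]) ? t.left[node] : t.right[node];
  return t.value[node];
}

// Fisher-Yates shuffle of an index vector using R's RNG.
void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& y;   // target (response or residual)
  int max_depth, min_split, min_leaf, mtry;
  const std::vector<int>& allowed; // candidate feature columns
  std::vector<double>& importance; // accumulated raw impurity decrease (SSE units)
  Tree tree;

  Builder(const NumericMatrix& X_, const std::vector<double>& y_, int max_depth_,
          int min_split_, int min_leaf_, int mtry_, const std::vector<int>& allowed_,
          std::vector<double>& imp_)
    : X(X_), y(y_), max_depth(max_depth_), min_split(min_split_),
      min_leaf(min_leaf_), mtry(mtry_), allowed(allowed_), importance(imp_) {}

  int new_node(double value, double cover) {
    tree.feature.push_back(-1); tree.threshold.push_back(0.0);
    tree.left.push_back(-1);    tree.right.push_back(-1);
    tree.value.push_back(value); tree.cover.push_back(cover);
    return tree.n_nodes() - 1;
  }

  void build(std::vector<int>& idx, int depth, int node_id) {
    const int n = (int)idx.size();
    double s = 0.0, s2 = 0.0;
    for (int i : idx) { s += y[i]; s2 += y[i] * y[i]; }
    const double node_score = s * s / n;   // n * mean^2; SSE = s2 - node_score

    if (depth >= max_depth || n < min_split || s2 - node_score <= 1e-12) return;

    // examine up to mtry non-constant candidate features, in random order
    std::vector<int> order(allowed);
    shuffle_idx(order);
    int examined = 0;
    int best_f = -1; double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double,double> > xy(n);

    for (int f : order) {
      if (examined >= mtry && best_f >= 0) break;
      for (int i = 0; i < n; ++i) xy[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(xy.begin(), xy.end());
      if (xy.front().first == xy.back().first) continue; // constant in node
      ++examined;
      double sl = 0.0; int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second; ++nl;
        if (xy[i].first == xy[i + 1].first) continue;
        int nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        double sr = s - sl;
        double gain = sl * sl / nl + sr * sr / nr - node_score;
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (xy[i].first + xy[i + 1].first);
        }
      }
      if (examined >= mtry && best_f >= 0) break;
    }
    if (best_f < 0) return;

    importance[best_f] += best_gain;  // = SSE_parent - SSE_left - SSE_right

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    { std::vector<int>().swap(idx); } // free before recursing

    double sl = 0.0;
    for (int i : lidx) sl += y[i];
    int lid = new_node(sl / lidx.size(), (double)lidx.size());
    int rid = new_node((s - sl) / ridx.size(), (double)ridx.size());
    tree.feature[node_id] = best_f;
    tree.threshold[node_id] = best_thr;
    tree.left[node_id] = lid;
    tree.right[node_id] = rid;
    build(lidx, depth + 1, lid);
    build(ridx, depth + 1, rid);
  }

  Tree run(std::vector<int> idx) {
    double s = 0.0;
    for (int i : idx) s += y[i];
    int root = new_node(s / idx.size(), (double)idx.size());
    build(idx, 0, root);
    return tree;
  }
};

std::vector<int> seq_idx(int n) {
  std::vector<int> v(n);
  for (int i = 0; i < n; ++i) v[i] = i;
  return v;
}

} // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int max_depth, int min_split, int min_leaf, bool bootstrap) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> yy(y.begin(), y.end());
  std::vector<int> allowed = seq_idx(p);
  List trees(n_trees);
  NumericVector imp(p);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx;
    if (bootstrap) {
      idx.resize(n);
      for (int i = 0; i < n; ++i) {
        int j = (int)std::floor(unif_rand() * n);
        idx[i] = (j >= n) ? n - 1 : j;
      }
    } else idx = seq_idx(n);
    std::vector<double> tree_imp(p, 0.0);
    Builder b(X, yy, max_depth, min_split, min_leaf, mtry, allowed, tree_imp);
    trees[t] = tree_to_matrix(b.run(idx));
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += tree_imp[j];
    if (tot > 0)  // per-tree normalization, then average across trees
      for (int j = 0; j < p; ++j) imp[j] += tree_imp[j] / tot / n_trees;
  }
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["init"] = 0.0, _["tree_weight"] = 1.0 / n_trees);
}

// [[Rcpp::export]]
List cpp_gbm_fit(NumericMatrix X, NumericVector y, int n_trees, double learning_rate,
                 int max_depth, int min_split, int min_leaf,
                 double subsample, double colsample) {
  const int n = X.nrow(), p = X.ncol();
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;
  std::vector<double> resid(n);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - init;

  List trees(n_trees);
  NumericVector imp(p);
  const int n_sub = std::max(2, (int)std::floor(subsample * n));
  const int p_sub = std::max(1, (int)std::floor(colsample * p));

  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows = seq_idx(n);
    if (n_sub < n) { shuffle_idx(rows); rows.resize(n_sub); }
    std::vector<int> cols = seq_idx(p);
    if (p_sub < p) { shuffle_idx(cols); cols.resize(p_sub); }
    std::vector<double> tree_imp(p, 0.0);
    Builder b(X, resid, max_depth, min_split, min_leaf, (int)cols.size(), cols, tree_imp);
    Tree tr = b.run(rows);
    trees[t] = tree_to_matrix(tr);
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += tree_imp[j];
    if (tot > 0)
      for (int j = 0; j < p; ++j) imp[j] += tree_imp[j] / tot / n_trees;
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.feature[node] >= 0)
        node = (X(i, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
      resid[i] -= learning_rate * tr.value[node];
    }
  }
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["init"] = init, _["tree_weight"] = learning_rate);
}

// [[Rcpp::export]]
NumericVector cpp_ensemble_predict(List trees, NumericMatrix X,
                                   double tree_weight, double init) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> ts;
  for (int t = 0; t < trees.size(); ++t)
    ts.push_back(tree_from_matrix(as<NumericMatrix>(trees[t])));
  NumericVector out(n, init);
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    double s = 0.0;
    for (size_t t = 0; t < ts.size(); ++t) s += predict_tree(ts[t], xrow.data());
    out[i] += tree_weight * s;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact tree-path Shapley attribution (polynomial-time path algorithm).
// The path bookkeeping follows the published recursive EXTEND/UNWIND scheme;
// correctness is pinned by brute-force Shapley oracles in the test suite.
// condition: 0 none; +1 feature forced present; -1 feature forced absent.
// ---------------------------------------------------------------------------
namespace {

struct PathElement {
  int feature_index;
  double zero_fraction, one_fraction, pweight;
};

void extend_path(PathElement* up, int unique_depth, double zero_fraction,
                 double one_fraction, int feature_index) {
  up[unique_depth].feature_index = feature_index;
  up[unique_depth].zero_fraction = zero_fraction;
  up[unique_depth].one_fraction = one_fraction;
  up[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  for (int i = unique_depth - 1; i >= 0; --i) {
    up[i + 1].pweight += one_fraction * up[i].pweight * (i + 1) / (double)(unique_depth + 1);
    up[i].pweight = zero_fraction * up[i].pweight * (unique_depth - i) / (double)(unique_depth + 1);
  }
}

void unwind_path(PathElement* up, int unique_depth, int path_index) {
  const double one_fraction = up[path_index].one_fraction;
  const double zero_fraction = up[path_index].zero_fraction;
  double next_one_portion = up[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = up[i].pweight;
      up[i].pweight = next_one_portion * (unique_depth + 1) / (double)((i + 1) * one_fraction);
      next_one_portion = tmp - up[i].pweight * zero_fraction * (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      up[i].pweight = up[i].pweight * (unique_depth + 1) / (double)(zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    up[i].feature_index = up[i + 1].feature_index;
    up[i].zero_fraction = up[i + 1].zero_fraction;
    up[i].one_fraction = up[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement* up, int unique_depth, int path_index) {
  const double one_fraction = up[path_index].one_fraction;
  const double zero_fraction = up[path_index].zero_fraction;
  double next_one_portion = up[unique_depth].pweight;
  double total = 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0.0) {
      const double tmp = next_one_portion * (unique_depth + 1)
                         / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = up[i].pweight
                         - tmp * zero_fraction * (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      total += up[i].pweight * (unique_depth + 1)
               / (double)(zero_fraction * (unique_depth - i));
    }
  }
  return total;
}

void tree_shap_recursive(const Tree& tree, const double* x, double* phi,
                         int node_index, int unique_depth, PathElement* parent_unique_path,
                         double parent_zero_fraction, double parent_one_fraction,
                         int parent_feature_index, int condition, int condition_feature,
                         double condition_fraction) {
  if (condition_fraction == 0.0) return;

  PathElement* unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1, unique_path);
  if (condition == 0 || condition_feature != parent_feature_index)
    extend_path(unique_path, unique_depth, parent_zero_fraction,
                parent_one_fraction, parent_feature_index);

  const int split_index = tree.feature[node_index];

  if (split_index < 0) { // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement& el = unique_path[i];
      phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction)
                               * tree.value[node_index] * condition_fraction;
    }
    return;
  }

  const int hot_index = (x[split_index] <= tree.threshold[node_index])
                          ? tree.left[node_index] : tree.right[node_index];
  const int cold_index = (hot_index == tree.left[node_index])
                          ? tree.right[node_index] : tree.left[node_index];
  const double w = tree.cover[node_index];
  const double hot_zero_fraction = tree.cover[hot_index] / w;
  const double cold_zero_fraction = tree.cover[cold_index] / w;
  double incoming_zero_fraction = 1.0, incoming_one_fraction = 1.0;

  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == split_index) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  double hot_condition_fraction = condition_fraction;
  double cold_condition_fraction = condition_fraction;
  if (condition > 0 && split_index == condition_feature) {
    cold_condition_fraction = 0.0;
    unique_depth -= 1;
  } else if (condition < 0 && split_index == condition_feature) {
    hot_condition_fraction *= hot_zero_fraction;
    cold_condition_fraction *= cold_zero_fraction;
    unique_depth -= 1;
  }

  tree_shap_recursive(tree, x, phi, hot_index, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction, incoming_one_fraction,
                      split_index, condition, condition_feature, hot_condition_fraction);
  tree_shap_recursive(tree, x, phi, cold_index, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_index, condition, condition_feature, cold_condition_fraction);
}

int tree_max_depth(const Tree& t, int node, int d) {
  if (t.feature[node] < 0) return d;
  return std::max(tree_max_depth(t, t.left[node], d + 1),
                  tree_max_depth(t, t.right[node], d + 1));
}

double tree_expected_value(const Tree& t) {
  double ev = 0.0;
  for (int i = 0; i < t.n_nodes(); ++i)
    if (t.feature[i] < 0) ev += t.cover[i] / t.cover[0] * t.value[i];
  return ev;
}

void tree_shap(const Tree& tree, const double* x, double* phi,
               std::vector<PathElement>& storage, int condition, int condition_feature) {
  tree_shap_recursive(tree, x, phi, 0, 0, storage.data(), 1.0, 1.0, -1,
                      condition, condition_feature, 1.0);
}

} // namespace

// [[Rcpp::export]]
List cpp_tree_shap_matrix(List trees, NumericMatrix X, double tree_weight, double init) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> ts;
  int maxd = 0;
  double base = init;
  for (int t = 0; t < trees.size(); ++t) {
    ts.push_back(tree_from_matrix(as<NumericMatrix>(trees[t])));
    maxd = std::max(maxd, tree_max_depth(ts.back(), 0, 0));
    base += tree_weight * tree_expected_value(ts.back());
  }
  std::vector<PathElement> storage((maxd + 3) * (maxd + 4));
  NumericMatrix phi(n, p);
  std::vector<double> xrow(p), ph(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(ph.begin(), ph.end(), 0.0);
    for (size_t t = 0; t < ts.size(); ++t)
      tree_shap(ts[t], xrow.data(), ph.data(), storage, 0, -1);
    for (int j = 0; j < p; ++j) phi(i, j) = tree_weight * ph[j];
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Pairwise Shapley interaction values: for each feature i used by the
// ensemble, the attribution vector is recomputed with i conditioned present
// and conditioned absent; half the difference gives the off-diagonal row, and
// the diagonal absorbs the remainder so that every row sums to the plain
// attribution. The result is symmetrized and the diagonal re-closed, making
// symmetry and row-sum reconciliation exact identities.
// [[Rcpp::export]]
NumericVector cpp_shap_interaction_tensor(List trees, NumericMatrix X,
                                          double tree_weight, double init) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<Tree> ts;
  int maxd = 0;
  for (int t = 0; t < trees.size(); ++t) {
    ts.push_back(tree_from_matrix(as<NumericMatrix>(trees[t])));
    maxd = std::max(maxd, tree_max_depth(ts.back(), 0, 0));
  }
  std::vector<bool> used(p, false);
  for (size_t t = 0; t < ts.size(); ++t)
    for (int k = 0; k < ts[t].n_nodes(); ++k)
      if (ts[t].feature[k] >= 0) used[ts[t].feature[k]] = true;
  std::vector<int> used_idx;
  for (int j = 0; j < p; ++j) if (used[j]) used_idx.push_back(j);

  std::vector<PathElement> storage((maxd + 3) * (maxd + 4));
  NumericVector out(Dimension(n, p, p)); // zero-initialized
  std::vector<double> xrow(p), phi(p), phi_on(p), phi_off(p);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (size_t t = 0; t < ts.size(); ++t)
      tree_shap(ts[t], xrow.data(), phi.data(), storage, 0, -1);

    for (size_t u = 0; u < used_idx.size(); ++u) {
      const int f = used_idx[u];
      std::fill(phi_on.begin(), phi_on.end(), 0.0);
      std::fill(phi_off.begin(), phi_off.end(), 0.0);
      for (size_t t = 0; t < ts.size(); ++t) {
        tree_shap(ts[t], xrow.data(), phi_on.data(), storage, 1, f);
        tree_shap(ts[t], xrow.data(), phi_off.data(), storage, -1, f);
      }
      for (int j = 0; j < p; ++j) {
        if (j == f) continue;
        out[i + (size_t)n * (f + (size_t)p * j)] =
          tree_weight * 0.5 * (phi_on[j] - phi_off[j]);
      }
    }
    // symmetrize off-diagonals, then close each row on the plain attribution
    for (int a = 0; a < p; ++a) {
      for (int b = a + 1; b < p; ++b) {
        size_t iab = i + (size_t)n * (a + (size_t)p * b);
        size_t iba = i + (size_t)n * (b + (size_t)p * a);
        double v = 0.5 * (out[iab] + out[iba]);
        out[iab] = v; out[iba] = v;
      }
    }
    for (int a = 0; a < p; ++a) {
      double rs = 0.0;
      for (int b = 0; b < p; ++b)
        if (b != a) rs += out[i + (size_t)n * (a + (size_t)p * b)];
      out[i + (size_t)n * (a + (size_t)p * a)] = tree_weight * phi[a] - rs;
    }
  }
  return out;
}
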