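// Exact path-dependent TreeSHAP for regression tree ensembles
// (Lundberg et al., polynomial-time algorithm over decision paths, with
// per-node covers taken from the tree's own in-bag training sample).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;  // fraction of cover flowing through when feature absent
  double one_fraction;   // 1 if x follows this path, else 0
  double pweight;
};

// reciprocals of small integers; path lengths are bounded by the number of
// distinct features on a root-leaf path (+1), far below 256
static const int kMaxPath = 256;
static double kRecip[kMaxPath];
static const bool kRecipInit = [] {
  kRecip[0] = 0.0;
  for (int i = 1; i < kMaxPath; ++i) kRecip[i] = 1.0 / i;
  return true;
}();

static inline void extend_path(PathElement *unique_path, unsigned unique_depth,
                               double zero_fraction, double one_fraction,
                               int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = (unique_depth == 0 ? 1.0 : 0.0);
  const double rd = kRecip[unique_depth + 1];
  for (int i = unique_depth - 1; i >= 0; --i) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
      (i + 1) * rd;
    unique_path[i].pweight *= zero_fraction * (unique_depth - i) * rd;
  }
}

static inline void unwind_path(PathElement *unique_path, unsigned unique_depth,
                               unsigned path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  const double rd = kRecip[unique_depth + 1];
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) *
        kRecip[i + 1] / one_fraction;
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
        (unique_depth - i) * rd;
    } else {
      unique_path[i].pweight = unique_path[i].pweight * (unique_depth + 1) *
        kRecip[unique_depth - i] / zero_fraction;
    }
  }
  for (unsigned i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

static inline double unwound_path_sum(const PathElement *unique_path,
                                      unsigned unique_depth,
                                      unsigned path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  if (one_fraction != 0) {
    const double ro = 1.0 / one_fraction;
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one_portion * kRecip[i + 1] * ro;
      total += tmp;
      next_one_portion = unique_path[i].pweight -
        tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    const double rz = 1.0 / zero_fraction;
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += unique_path[i].pweight * kRecip[unique_depth - i] * rz;
    }
  }
  return total * (unique_depth + 1);
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void shap_recursive(const Tree &tr, const double *x, double *phi,
                           int node, unsigned unique_depth,
                           PathElement *parent_unique_path,
                           double parent_zero_fraction,
                           double parent_one_fraction,
                           int parent_feature_index) {
  PathElement *unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (tr.left[node] < 0) {  // leaf
    for (unsigned i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement &el = unique_path[i];
      phi[el.feature_index] +=
        w * (el.one_fraction - el.zero_fraction) * tr.value[node];
    }
    return;
  }
  const int f = tr.feature[node];
  const int hot = (x[f] <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero_fraction = tr.cover[hot] / w;
  const double cold_zero_fraction = tr.cover[cold] / w;
  double incoming_zero_fraction = 1, incoming_one_fraction = 1;

  unsigned path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (unique_path[path_index].feature_index == f) break;
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }
  shap_recursive(tr, x, phi, hot, unique_depth + 1, unique_path,
                 hot_zero_fraction * incoming_zero_fraction,
                 incoming_one_fraction, f);
  shap_recursive(tr, x, phi, cold, unique_depth + 1, unique_path,
                 cold_zero_fraction * incoming_zero_fraction, 0.0, f);
}

static int tree_max_depth(const Tree &tr, int node) {
  if (tr.left[node] < 0) return 1;
  return 1 + std::max(tree_max_depth(tr, tr.left[node]),
                      tree_max_depth(tr, tr.right[node]));
}

// SHAP values of a forest (mean over trees) for rows of X.
// Each tree: 0-based child/feature indices, children = -1 at leaves,
// `cover` = per-node training weight. Returns an (n, p) matrix whose row sums
// plus the forest base value reproduce the forest prediction.
// [[Rcpp::export]]
List treeshap_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericMatrix phi(n, p);
  double base = 0;
  std::vector<double> xrow(p);
  for (int k = 0; k < ntree; ++k) {
    List t = trees[k];
    IntegerVector left = t["left"], right = t["right"], feature = t["feature"];
    NumericVector threshold = t["threshold"], value = t["value"],
      cover = t["cover"];
    Tree tr{left.begin(), right.begin(), feature.begin(),
            threshold.begin(), value.begin(), cover.begin()};
    // base value: cover-weighted mean over leaves = conditional mean at root
    double b = 0;
    for (int j = 0; j < left.size(); ++j)
      if (left[j] < 0) b += cover[j] * value[j];
    b /= cover[0];
    base += b / ntree;

    const int maxd = tree_max_depth(tr, 0);
    std::vector<PathElement> paths((maxd + 2) * (maxd + 3) / 2);
    std::vector<double> phirow(p);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      shap_recursive(tr, xrow.data(), phirow.data(), 0, 0, paths.data(),
                     1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j] / ntree;
    }
  }
  return List::create(_["phi"] = phi, _["base"] = base);
}

// Per-node training cover: routes every row of X down the tree accumulating w.
// [[Rcpp::export]]
NumericVector treeshap_cover(IntegerVector left, IntegerVector right,
                             IntegerVector feature, NumericVector threshold,
                             NumericMatrix X, NumericVector w) {
  const int n = X.nrow();
  NumericVector cover(left.size());
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0) continue;
    int node = 0;
    for (;;) {
      cover[node] += w[i];
      if (left[node] < 0) break;
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
  }
  return cover;
}

// Forest prediction from the extracted arrays (mean of per-tree leaf values);
// used to verify additivity independently of randomForest's predict().
// [[Rcpp::export]]
NumericVector treeshap_predict(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int k = 0; k < ntree; ++k) {
    List t = trees[k];
    IntegerVector left = t["left"], right = t["right"], feature = t["feature"];
    NumericVector threshold = t["threshold"], value = t["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (left[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
      out[i] += value[node] / ntree;
    }
  }
  return out;
}
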