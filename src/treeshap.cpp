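// Exact path-dependent Shapley attributions for ensembles of regression
// trees (TreeSHAP). Conditional expectations follow the tree's own cover
// weights (no background dataset). Forests are passed as flat node arrays
// with 0-based global indices; children/feature are -1 at leaves.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathEl {
  int feat;
  double zero; // fraction of paths flowing through when feature is unknown
  double one;  // fraction when the feature matches the instance
  double w;    // permutation weight
};

static void extend_path(std::vector<PathEl> &m, int unique_depth,
                        double pz, double po, int pi) {
  m[unique_depth].feat = pi;
  m[unique_depth].zero = pz;
  m[unique_depth].one = po;
  m[unique_depth].w = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / (double)(unique_depth + 1);
    m[i].w = pz * m[i].w * (unique_depth - i) / (double)(unique_depth + 1);
  }
}

static void unwind_path(std::vector<PathEl> &m, int unique_depth, int path_index) {
  const double po = m[path_index].one;
  const double pz = m[path_index].zero;
  double next_one = m[unique_depth].w;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (po != 0.0) {
      const double tmp = m[i].w;
      m[i].w = next_one * (unique_depth + 1) / ((i + 1) * po);
      next_one = tmp - m[i].w * pz * (unique_depth - i) / (double)(unique_depth + 1);
    } else {
      m[i].w = m[i].w * (unique_depth + 1) / (pz * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    m[i].feat = m[i + 1].feat;
    m[i].zero = m[i + 1].zero;
    m[i].one = m[i + 1].one;
  }
}

static double unwound_sum(const std::vector<PathEl> &m, int unique_depth,
                          int path_index) {
  const double po = m[path_index].one;
  const double pz = m[path_index].zero;
  double next_one = m[unique_depth].w;
  double total = 0.0;
  if (po != 0.0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp = next_one * (unique_depth + 1) / ((i + 1) * po);
      total += tmp;
      next_one = m[i].w - tmp * pz * (unique_depth - i) / (double)(unique_depth + 1);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += m[i].w * (unique_depth + 1) / (pz * (unique_depth - i));
    }
  }
  return total;
}

struct Forest {
  const int *cl, *cr, *feat;
  const double *split, *value, *cover;
};

static void shap_recurse(const Forest &T, const double *x, double *phi,
                         int node, int unique_depth,
                         std::vector<PathEl> m, // copied per call by design
                         double pz, double po, int pi) {
  if ((int)m.size() < unique_depth + 1) m.resize(unique_depth + 1);
  extend_path(m, unique_depth, pz, po, pi);
  if (T.feat[node] < 0) { // leaf
    const double v = T.value[node];
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_sum(m, unique_depth, i);
      phi[m[i].feat] += w * (m[i].one - m[i].zero) * v;
    }
    return;
  }
  const int f = T.feat[node];
  int hot, cold;
  if (x[f] <= T.split[node]) {
    hot = T.cl[node];
    cold = T.cr[node];
  } else {
    hot = T.cr[node];
    cold = T.cl[node];
  }
  double iz = 1.0, io = 1.0;
  int path_index = 1;
  for (; path_index <= unique_depth; ++path_index) {
    if (m[path_index].feat == f) break;
  }
  if (path_index <= unique_depth) {
    iz = m[path_index].zero;
    io = m[path_index].one;
    unwind_path(m, unique_depth, path_index);
    unique_depth -= 1;
  }
  const double cn = T.cover[node];
  shap_recurse(T, x, phi, hot, unique_depth + 1, m, iz * T.cover[hot] / cn, io, f);
  shap_recurse(T, x, phi, cold, unique_depth + 1, m, iz * T.cover[cold] / cn, 0.0, f);
}

// Per-node training cover by routing rows from each tree root.
// [[Rcpp::export]]
NumericVector cpp_forest_cover(IntegerVector child_left, IntegerVector child_right,
                               IntegerVector feature, NumericVector split,
                               IntegerVector roots, NumericMatrix X) {
  const int n_nodes = child_left.size();
  const int n = X.nrow();
  NumericVector cover(n_nodes);
  for (int t = 0; t < roots.size(); ++t) {
    const int root = roots[t];
    for (int i = 0; i < n; ++i) {
      int node = root;
      for (;;) {
        cover[node] += 1.0;
        const int f = feature[node];
        if (f < 0) break;
        node = (X(i, f) <= split[node]) ? child_left[node] : child_right[node];
      }
    }
  }
  return cover;
}

// Shapley contributions for every row of X under a forest; the returned
// matrix has one column per feature plus a final base-value column (the
// cover-weighted mean leaf value, averaged over trees when `average`).
// [[Rcpp::export]]
NumericMatrix cpp_forest_shap(IntegerVector child_left, IntegerVector child_right,
                              IntegerVector feature, NumericVector split,
                              NumericVector value, NumericVector cover,
                              IntegerVector roots, NumericMatrix X,
                              bool average) {
  const int n = X.nrow();
  const int p = X.ncol();
  const int n_trees = roots.size();
  NumericMatrix out(n, p + 1);
  Forest T = {child_left.begin(), child_right.begin(), feature.begin(),
              split.begin(), value.begin(), cover.begin()};

  // base value: cover-weighted mean of leaf values, walked from each root
  double base = 0.0;
  {
    std::vector<int> stack;
    for (int t = 0; t < n_trees; ++t) {
      const double root_cover = cover[roots[t]];
      stack.push_back(roots[t]);
      while (!stack.empty()) {
        const int node = stack.back();
        stack.pop_back();
        if (feature[node] < 0) {
          base += cover[node] / root_cover * value[node];
        } else {
          stack.push_back(child_left[node]);
          stack.push_back(child_right[node]);
        }
      }
    }
    if (average) base /= n_trees;
  }

  std::vector<double> x(p), phi(p);
  std::vector<PathEl> m0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int t = 0; t < n_trees; ++t) {
      if (feature[roots[t]] < 0) continue; // stump root leaf contributes only base
      shap_recurse(T, x.data(), phi.data(), roots[t], 0, m0, 1.0, 1.0, -1);
    }
    const double s = average ? 1.0 / n_trees : 1.0;
    for (int j = 0; j < p; ++j) out(i, j) = phi[j] * s;
    out(i, p) = base;
  }
  return out;
}
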