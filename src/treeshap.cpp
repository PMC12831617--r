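// Path-dependent TreeSHAP for binary decision trees (EXTEND/UNWIND
// formulation). Attributes a tree ensemble's prediction for one sample to
// the input features; node covers are reconstructed by routing weighted
// training samples down each tree, which makes the attributions satisfy
// exact local accuracy: base + sum(phi) == ensemble prediction.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElem {
  int d;        // feature index of the split that created this element
  double z;     // fraction of zero (cover-weighted) paths that flow through
  double o;     // fraction of one (observed) paths that flow through
  double w;     // permutation weight
};

// Grow the path by one split. l is the length before extension.
static void path_extend(std::vector<PathElem> &m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  m.push_back({pi, pz, po, l == 0 ? 1.0 : 0.0});
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

// Remove the element at position k, undoing its effect on the weights.
static void path_unwind(std::vector<PathElem> &m, int k) {
  const int L = static_cast<int>(m.size());
  const double o = m[k].o, z = m[k].z;
  double n = m[L - 1].w;
  for (int j = L - 2; j >= 0; --j) {
    if (o != 0.0) {
      const double t = m[j].w;
      m[j].w = n * L / static_cast<double>((j + 1) * o);
      n = t - m[j].w * z * (L - 1 - j) / static_cast<double>(L);
    } else {
      m[j].w = m[j].w * L / (z * (L - 1 - j));
    }
  }
  for (int j = k; j < L - 1; ++j) {
    m[j].d = m[j + 1].d;
    m[j].z = m[j + 1].z;
    m[j].o = m[j + 1].o;
  }
  m.pop_back();
}

// Sum of weights after unwinding element k (path left untouched).
static double path_unwound_sum(const std::vector<PathElem> &m, int k) {
  std::vector<PathElem> c(m);
  path_unwind(c, k);
  double s = 0.0;
  for (const PathElem &e : c) s += e.w;
  return s;
}

struct Tree {
  const int *left, *right, *var;
  const double *thr, *value;
  std::vector<double> cover;
};

static void shap_recurse(const Tree &tree, const double *x, double *phi,
                         std::vector<PathElem> m,  // by value: parent copy
                         int node, double pz, double po, int pi) {
  path_extend(m, pz, po, pi);
  if (tree.var[node] < 0) {  // leaf
    const double v = tree.value[node];
    for (int k = 1; k < static_cast<int>(m.size()); ++k) {
      const double w = path_unwound_sum(m, k);
      phi[m[k].d] += w * (m[k].o - m[k].z) * v;
    }
    return;
  }
  const int d = tree.var[node];
  const int lc = tree.left[node], rc = tree.right[node];
  const int hot = (x[d] <= tree.thr[node]) ? lc : rc;
  const int cold = (hot == lc) ? rc : lc;
  double iz = 1.0, io = 1.0;
  for (int k = 1; k < static_cast<int>(m.size()); ++k) {
    if (m[k].d == d) {
      iz = m[k].z;
      io = m[k].o;
      path_unwind(m, k);
      break;
    }
  }
  const double rj = tree.cover[node];
  shap_recurse(tree, x, phi, m, hot, iz * tree.cover[hot] / rj, io, d);
  shap_recurse(tree, x, phi, m, cold, iz * tree.cover[cold] / rj, 0.0, d);
}

// Route weighted training samples down the tree to obtain node covers.
static std::vector<double> tree_covers(const int *left, const int *right,
                                       const int *var, const double *thr,
                                       int n_nodes, const NumericMatrix &X,
                                       const NumericVector &w) {
  std::vector<double> cover(n_nodes, 0.0);
  const int n = X.nrow();
  for (int s = 0; s < n; ++s) {
    if (w[s] <= 0) continue;
    int node = 0;
    cover[0] += w[s];
    while (var[node] >= 0) {
      node = (X(s, var[node]) <= thr[node]) ? left[node] : right[node];
      cover[node] += w[s];
    }
  }
  return cover;
}

// trees: list of lists with 0-based integer vectors `left`, `right`, `var`
// (-1 marks a leaf), numeric `thr`, `value` (leaf prediction) and `weight`
// (per-training-sample routing weight, e.g. in-bag counts).
// [[Rcpp::export]]
List treeshap_forest_cpp(List trees, NumericMatrix X, NumericMatrix X_train) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> xrow(p);

  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector left = tr["left"], right = tr["right"], var = tr["var"];
    NumericVector thr = tr["thr"], value = tr["value"], w = tr["weight"];
    Tree tree{left.begin(), right.begin(), var.begin(),
              thr.begin(), value.begin(), {}};
    tree.cover = tree_covers(tree.left, tree.right, tree.var, tree.thr,
                             left.size(), X_train, w);
    if (tree.cover[0] <= 0) stop("tree %d has zero root cover", t + 1);

    // expected leaf value under the cover distribution
    double ev = 0.0;
    for (int j = 0; j < left.size(); ++j) {
      if (tree.var[j] < 0) ev += tree.cover[j] * tree.value[j];
    }
    base += ev / tree.cover[0];

    for (int s = 0; s < n; ++s) {
      for (int j = 0; j < p; ++j) xrow[j] = X(s, j);
      std::vector<double> phirow(p, 0.0);
      std::vector<PathElem> m;
      m.reserve(64);
      shap_recurse(tree, xrow.data(), phirow.data(), m, 0, 1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(s, j) += phirow[j];
    }
  }
  const double invT = 1.0 / static_cast<double>(T);
  for (int s = 0; s < n; ++s)
    for (int j = 0; j < p; ++j) phi(s, j) *= invT;
  return List::create(_["phi"] = phi, _["base"] = base * invT);
}
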