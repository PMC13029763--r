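// Path-dependent TreeSHAP over a forest of binary decision trees.
// Node "covers" (reference-sample counts) are reconstructed by routing a
// reference matrix through each tree; the expected value is the
// cover-weighted leaf mean. Zero-cover branches carry no expectation mass:
// cold descents into them are pruned, hot descents continue with zero
// fraction, preserving local accuracy (sum(phi) + base == prediction).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *m, unsigned depth, double pz, double po,
                        int pi) {
  m[depth].feature_index = pi;
  m[depth].zero_fraction = pz;
  m[depth].one_fraction = po;
  m[depth].pweight = (depth == 0 ? 1.0 : 0.0);
  for (int i = depth - 1; i >= 0; --i) {
    m[i + 1].pweight += po * m[i].pweight * (i + 1) /
      static_cast<double>(depth + 1);
    m[i].pweight = pz * m[i].pweight * (depth - i) /
      static_cast<double>(depth + 1);
  }
}

static void unwind_path(PathElement *m, unsigned depth, unsigned idx) {
  const double po = m[idx].one_fraction;
  const double pz = m[idx].zero_fraction;
  double next_one = m[depth].pweight;
  for (int i = depth - 1; i >= 0; --i) {
    if (po != 0) {
      const double tmp = m[i].pweight;
      m[i].pweight = next_one * (depth + 1) /
        static_cast<double>((i + 1) * po);
      next_one = tmp - m[i].pweight * pz * (depth - i) /
        static_cast<double>(depth + 1);
    } else if (pz != 0) {
      m[i].pweight = (m[i].pweight * (depth + 1)) /
        static_cast<double>(pz * (depth - i));
    } else {
      m[i].pweight = 0.0;
    }
  }
  for (unsigned i = idx; i < depth; ++i) {
    m[i].feature_index = m[i + 1].feature_index;
    m[i].zero_fraction = m[i + 1].zero_fraction;
    m[i].one_fraction = m[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *m, unsigned depth,
                               unsigned idx) {
  const double po = m[idx].one_fraction;
  const double pz = m[idx].zero_fraction;
  double next_one = m[depth].pweight;
  double total = 0;
  if (po != 0) {
    for (int i = depth - 1; i >= 0; --i) {
      const double tmp = next_one / static_cast<double>((i + 1) * po);
      total += tmp;
      next_one = m[i].pweight - tmp * pz * (depth - i);
    }
  } else if (pz != 0) {
    for (int i = depth - 1; i >= 0; --i) {
      total += m[i].pweight / (pz * (depth - i));
    }
  }
  return total * (depth + 1);
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value;
  const double *cover;
};

static void tree_shap_recursive(const Tree &t, const double *x, double *phi,
                                int node, unsigned depth,
                                PathElement *parent_path, double pz,
                                double po, int pi) {
  PathElement *path = parent_path + depth + 1;
  std::copy(parent_path, parent_path + depth + 1, path);
  extend_path(path, depth, pz, po, pi);

  if (t.left[node] < 0) { // leaf
    const double v = t.value[node];
    for (unsigned i = 1; i <= depth; ++i) {
      const double w = unwound_path_sum(path, depth, i);
      const PathElement &el = path[i];
      if (el.feature_index >= 0) {
        phi[el.feature_index] += w * (el.one_fraction - el.zero_fraction) * v;
      }
    }
    return;
  }

  const int f = t.feature[node];
  int hot, cold;
  if (x[f] <= t.threshold[node]) {
    hot = t.left[node]; cold = t.right[node];
  } else {
    hot = t.right[node]; cold = t.left[node];
  }
  const double denom = t.cover[node];
  const double hot_zero = denom > 0 ? t.cover[hot] / denom : 0.0;
  const double cold_zero = denom > 0 ? t.cover[cold] / denom : 0.0;

  double iz = 1.0, io = 1.0;
  unsigned path_index = 0;
  for (; path_index <= depth; ++path_index) {
    if (path[path_index].feature_index == f) break;
  }
  if (path_index != depth + 1) {
    iz = path[path_index].zero_fraction;
    io = path[path_index].one_fraction;
    unwind_path(path, depth, path_index);
    depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot, depth + 1, path, hot_zero * iz, io, f);
  if (cold_zero * iz > 0) {
    tree_shap_recursive(t, x, phi, cold, depth + 1, path, cold_zero * iz,
                        0.0, f);
  }
}

static int tree_depth(const Tree &t, int node) {
  if (t.left[node] < 0) return 1;
  return 1 + std::max(tree_depth(t, t.left[node]),
                      tree_depth(t, t.right[node]));
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
List treeshap_cpp(List trees, NumericMatrix X, NumericMatrix Xref) {
  const int n = X.nrow(), p = X.ncol(), T = trees.size();
  NumericMatrix phi(n, p);
  double base = 0.0;
  std::vector<double> xrow(p), rrow(p);

  for (int ti = 0; ti < T; ++ti) {
    List tl = trees[ti];
    IntegerVector left = tl["left"], right = tl["right"],
      feature = tl["feature"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    const int nn = left.size();

    // covers from the reference matrix
    std::vector<double> cover(nn, 0.0);
    for (int r = 0; r < Xref.nrow(); ++r) {
      int node = 0;
      cover[0] += 1.0;
      while (left[node] >= 0) {
        node = (Xref(r, feature[node]) <= threshold[node]) ? left[node]
                                                           : right[node];
        cover[node] += 1.0;
      }
    }
    // expected value for this tree
    double ev = 0.0, tot = 0.0;
    for (int v = 0; v < nn; ++v) {
      if (left[v] < 0) { ev += cover[v] * value[v]; tot += cover[v]; }
    }
    if (tot > 0) base += ev / tot;

    Tree t;
    t.left = INTEGER(left); t.right = INTEGER(right);
    t.feature = INTEGER(feature);
    t.threshold = REAL(threshold); t.value = REAL(value);
    t.cover = cover.data();

    const int D = tree_depth(t, 0);
    std::vector<PathElement> arena((D + 3) * (D + 3));
    std::vector<double> phirow(p);

    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      std::fill(phirow.begin(), phirow.end(), 0.0);
      tree_shap_recursive(t, xrow.data(), phirow.data(), 0, 0, arena.data(),
                          1.0, 1.0, -1);
      for (int j = 0; j < p; ++j) phi(i, j) += phirow[j];
    }
  }

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) phi(i, j) /= T;
  }
  return List::create(Named("phi") = phi, Named("base") = base / T);
}
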