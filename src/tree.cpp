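#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Weighted binary CART grown best-first, used as the AdaBoost weak learner.
// Determinism contract: split-gain ties keep the lowest feature index, then
// the lowest threshold (features scanned in order, thresholds ascending);
// expansion ties among leaves keep the oldest node; leaf vote ties go to the
// negative (benign) class.

struct SplitInfo {
  int feature = -1;        // 0-based; -1 = no usable split
  double threshold = 0.0;  // goes left iff x <= threshold
  double gain = 0.0;       // weighted Gini impurity decrease
};

// Gini impurity mass of a node: 2 * w0 * w1 / (w0 + w1)
static inline double gini_mass(double w0, double w1) {
  double wt = w0 + w1;
  if (wt <= 0.0) return 0.0;
  return 2.0 * w0 * w1 / wt;
}

static SplitInfo best_split(const NumericMatrix& X, const IntegerVector& y,
                            const NumericVector& w, const std::vector<int>& idx) {
  SplitInfo best;
  const int p = X.ncol();
  const int n = (int)idx.size();
  if (n < 2) return best;

  double w0 = 0.0, w1 = 0.0;
  for (int i : idx) (y[i] == 1 ? w1 : w0) += w[i];
  const double parent = gini_mass(w0, w1);
  if (parent <= 1e-15) return best;

  std::vector<int> ord(idx);
  for (int j = 0; j < p; ++j) {
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, j) < X(b, j);
    });
    double l0 = 0.0, l1 = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      int i = ord[k];
      (y[i] == 1 ? l1 : l0) += w[i];
      double xk = X(i, j), xn = X(ord[k + 1], j);
      if (xn <= xk) continue;  // only split between distinct values
      double r0 = w0 - l0, r1 = w1 - l1;
      double gain = parent - gini_mass(l0, l1) - gini_mass(r0, r1);
      if (gain > best.gain + 1e-15) {
        best.gain = gain;
        best.feature = j;
        best.threshold = xk + (xn - xk) / 2.0;
      }
    }
  }
  return best;
}

struct Node {
  std::vector<int> idx;
  SplitInfo split;
  double w0 = 0.0, w1 = 0.0;
  int feature = -1;           // resolved on expansion
  double threshold = 0.0;
  int left = -1, right = -1;  // 0-based node ids
  bool open = true;           // still a candidate leaf
};

// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                  int max_nodes) {
  const int n = X.nrow();
  std::vector<Node> nodes;
  {
    Node root;
    root.idx.resize(n);
    for (int i = 0; i < n; ++i) root.idx[i] = i;
    for (int i = 0; i < n; ++i) (y[i] == 1 ? root.w1 : root.w0) += w[i];
    root.split = best_split(X, y, w, root.idx);
    nodes.push_back(std::move(root));
  }

  int n_branch = 0;
  while (n_branch < max_nodes) {
    // oldest node among those with the maximal positive gain
    int pick = -1;
    double best_gain = 1e-12;
    for (size_t k = 0; k < nodes.size(); ++k) {
      if (nodes[k].open && nodes[k].split.feature >= 0 &&
          nodes[k].split.gain > best_gain + 1e-15) {
        best_gain = nodes[k].split.gain;
        pick = (int)k;
      }
    }
    if (pick < 0) break;

    nodes[pick].open = false;
    nodes[pick].feature = nodes[pick].split.feature;
    nodes[pick].threshold = nodes[pick].split.threshold;

    Node L, R;
    for (int i : nodes[pick].idx) {
      if (X(i, nodes[pick].feature) <= nodes[pick].threshold) {
        L.idx.push_back(i);
        (y[i] == 1 ? L.w1 : L.w0) += w[i];
      } else {
        R.idx.push_back(i);
        (y[i] == 1 ? R.w1 : R.w0) += w[i];
      }
    }
    L.split = best_split(X, y, w, L.idx);
    R.split = best_split(X, y, w, R.idx);
    // push_back may reallocate `nodes`; never hold a reference across it
    int li = (int)nodes.size();
    nodes.push_back(std::move(L));
    int ri = (int)nodes.size();
    nodes.push_back(std::move(R));
    nodes[pick].left = li;
    nodes[pick].right = ri;
    ++n_branch;
  }

  const int m = (int)nodes.size();
  IntegerVector feature(m), left(m), right(m), vote(m);
  NumericVector threshold(m), gain(m), node_weight(m);
  for (int k = 0; k < m; ++k) {
    const Node& nd = nodes[k];
    feature[k] = nd.open ? -1 : nd.feature;
    threshold[k] = nd.open ? NA_REAL : nd.threshold;
    left[k] = nd.left;
    right[k] = nd.right;
    vote[k] = (nd.w1 > nd.w0) ? 1 : -1;
    gain[k] = nd.open ? 0.0 : nd.split.gain;
    node_weight[k] = nd.w0 + nd.w1;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["vote"] = vote,
                      _["gain"] = gain, _["node_weight"] = node_weight,
                      _["n_branch"] = n_branch);
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector vote, NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] >= 0) {
      k = (X(i, feature[k]) <= threshold[k]) ? left[k] : right[k];
    }
    out[i] = vote[k];
  }
  return out;
}
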