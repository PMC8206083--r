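// Weighted binary CART for effusion classification.
//
// Splits minimize weighted Gini impurity; leaves carry the weighted
// positive-class fraction, which is the score a tree contributes to a
// forest average. Feature subsampling (mtry) uses R's RNG so a set.seed()
// on the R side makes tree growth fully reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;  // 0-based node indices, -1 for leaf
  double score;     // weighted positive fraction
  int n;            // training rows reaching the node
};

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  const NumericVector& w;
  int max_depth, min_leaf, mtry;
  std::vector<Node> nodes;

  Grower(const NumericMatrix& X_, const IntegerVector& y_,
         const NumericVector& w_, int max_depth_, int min_leaf_, int mtry_)
      : X(X_), y(y_), w(w_), max_depth(max_depth_), min_leaf(min_leaf_),
        mtry(mtry_) {}

  // draw k of p feature indices without replacement (R RNG)
  std::vector<int> draw_features(int p, int k) {
    std::vector<int> idx(p);
    for (int j = 0; j < p; ++j) idx[j] = j;
    if (k >= p) return idx;
    for (int j = 0; j < k; ++j) {
      int pick = j + (int)(unif_rand() * (p - j));
      if (pick >= p) pick = p - 1;
      std::swap(idx[j], idx[pick]);
    }
    idx.resize(k);
    return idx;
  }

  int grow(std::vector<int>& rows, int depth) {
    double wpos = 0, wtot = 0;
    for (int i : rows) { wtot += w[i]; if (y[i] == 1) wpos += w[i]; }
    Node node;
    node.feature = -1; node.threshold = 0; node.left = node.right = -1;
    node.score = wtot > 0 ? wpos / wtot : 0.5;
    node.n = (int)rows.size();
    int self = (int)nodes.size();
    nodes.push_back(node);

    bool pure = (wpos <= 0) || (wpos >= wtot);
    if (depth >= max_depth || (int)rows.size() < 2 * min_leaf || pure)
      return self;

    const double parent_imp = wtot > 0 ? 2.0 * (wpos / wtot) * (1.0 - wpos / wtot) : 0.0;
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0;

    int p = X.ncol();
    std::vector<int> feats = draw_features(p, mtry > 0 ? mtry : p);
    std::vector<int> ord;
    for (int f : feats) {
      ord = rows;
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      double lw = 0, lp = 0;
      for (size_t k = 0; k + 1 < ord.size(); ++k) {
        int i = ord[k];
        lw += w[i]; if (y[i] == 1) lp += w[i];
        double xv = X(i, f), xn = X(ord[k + 1], f);
        if (xv == xn) continue;
        if ((int)(k + 1) < min_leaf || (int)(ord.size() - k - 1) < min_leaf)
          continue;
        double rw = wtot - lw, rp = wpos - lp;
        if (lw <= 0 || rw <= 0) continue;
        double il = 2.0 * (lp / lw) * (1.0 - lp / lw);
        double ir = 2.0 * (rp / rw) * (1.0 - rp / rw);
        double gain = parent_imp - (lw * il + rw * ir) / wtot;
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_thr = 0.5 * (xv + xn);
        }
      }
    }
    if (best_f < 0) return self;

    std::vector<int> lrows, rrows;
    for (int i : rows) {
      if (X(i, best_f) <= best_thr) lrows.push_back(i); else rrows.push_back(i);
    }
    if (lrows.empty() || rrows.empty()) return self;
    nodes[self].feature = best_f;
    nodes[self].threshold = best_thr;
    int li = grow(lrows, depth + 1);
    int ri = grow(rrows, depth + 1);
    nodes[self].left = li;
    nodes[self].right = ri;
    return self;
  }
};

} // namespace

// [[Rcpp::export(name = ".grow_tree_cpp")]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, NumericVector w,
                   int max_depth, int min_leaf, int mtry) {
  Grower g(X, y, w, max_depth, min_leaf, mtry);
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  g.grow(rows, 0);
  int m = (int)g.nodes.size();
  IntegerVector feature(m), left(m), right(m), n(m);
  NumericVector threshold(m), score(m);
  for (int k = 0; k < m; ++k) {
    feature[k] = g.nodes[k].feature;
    threshold[k] = g.nodes[k].threshold;
    left[k] = g.nodes[k].left;
    right[k] = g.nodes[k].right;
    score[k] = g.nodes[k].score;
    n[k] = g.nodes[k].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["score"] = score, _["n"] = n);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], score = tree["score"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = 0;
    while (feature[k] >= 0)
      k = X(i, feature[k]) <= threshold[k] ? left[k] : right[k];
    out[i] = score[k];
  }
  return out;
}
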