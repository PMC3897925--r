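#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Bagged CART classification forest: Gini splits, per-tree bootstrap bags,
// mtry-feature subsampling per split. Serves two purposes:
//  * importance source (Gini decrease with exact conservation, and per-tree
//    OOB permutation importance, raw and normalised);
//  * regularised forest selection: the gain of a gene not yet in the set F of
//    ensemble-used genes is multiplied by lambda <= 1, so redundant genes are
//    suppressed and F itself is the selection.
// All randomness from R's RNG (callers set.seed beforehand).

static inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> pred;         // majority class (valid at leaves)
};

// count-weighted Gini impurity: n * (1 - sum (n_c/n)^2)
static inline double gini_imp(const std::vector<double> &cnt, double n) {
  if (n <= 0) return 0.0;
  double s = 0;
  for (double c : cnt) s += c * c;
  return n - s / n;
}

struct Grower {
  const NumericMatrix &X;
  const IntegerVector &y;
  int n_classes, mtry, min_node;
  double lambda;
  std::vector<char> *used;       // penalty scope set F (forest or tree)
  std::vector<char> *used_union; // ensemble union (the selection)
  std::vector<double> *gini_sum; // per-gene impurity decrease
  double *total_dec;
  Tree tree;

  Grower(const NumericMatrix &X_, const IntegerVector &y_, int C, int mtry_,
         int min_node_, double lambda_, std::vector<char> *used_,
         std::vector<char> *used_union_, std::vector<double> *gini_sum_,
         double *total_dec_)
    : X(X_), y(y_), n_classes(C), mtry(mtry_), min_node(min_node_),
      lambda(lambda_), used(used_), used_union(used_union_),
      gini_sum(gini_sum_), total_dec(total_dec_) {}

  int new_node() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);
    return (int)tree.feature.size() - 1;
  }

  // idx: in-bag sample indices (with bootstrap multiplicity)
  int grow(std::vector<int> &idx) {
    int node = new_node();
    const int nn = (int)idx.size();
    std::vector<double> cnt(n_classes, 0.0);
    for (int i : idx) cnt[y[i]] += 1;
    int best_c = 0;
    for (int c = 1; c < n_classes; ++c)
      if (cnt[c] > cnt[best_c]) best_c = c; // tie -> lowest class index
    tree.pred[node] = best_c;

    double imp_parent = gini_imp(cnt, nn);
    if (nn < min_node || imp_parent <= 1e-12) return node;

    const int p = X.ncol();
    int m = mtry < p ? mtry : p;
    // draw m distinct candidate features (partial Fisher-Yates); under
    // regularisation the already-used set F always competes as well, so a
    // penalised newcomer must beat the incumbents, not just the random draw
    static thread_local std::vector<int> pool;
    pool.resize(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    std::vector<int> cand;
    std::vector<char> drawn(p, 0);
    for (int jj = 0; jj < m; ++jj) {
      int pick = jj + rand_int(p - jj);
      std::swap(pool[jj], pool[pick]);
      cand.push_back(pool[jj]);
      drawn[pool[jj]] = 1;
    }
    if (lambda < 1.0)
      for (int f = 0; f < p; ++f)
        if ((*used)[f] && !drawn[f]) cand.push_back(f);
    int best_f = -1;
    double best_thr = 0, best_reg = 1e-12, best_dec = 0;
    std::vector<int> ord(idx);
    std::vector<double> lc(n_classes);
    for (size_t jj = 0; jj < cand.size(); ++jj) {
      int f = cand[jj];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      std::fill(lc.begin(), lc.end(), 0.0);
      for (int i = 0; i + 1 < nn; ++i) {
        lc[y[ord[i]]] += 1;
        double v = X(ord[i], f), w = X(ord[i + 1], f);
        if (w <= v) continue;
        double nl = i + 1, nr = nn - nl;
        double sl = 0, sr = 0;
        for (int c = 0; c < n_classes; ++c) {
          sl += lc[c] * lc[c];
          double rc = cnt[c] - lc[c];
          sr += rc * rc;
        }
        double dec = imp_parent - (nl - sl / nl) - (nr - sr / nr);
        double reg = (*used)[f] ? dec : lambda * dec;
        if (reg > best_reg) {
          best_reg = reg;
          best_dec = dec;
          best_f = f;
          best_thr = (v + w) / 2;
        }
      }
    }
    if (best_f < 0) return node;

    (*used)[best_f] = 1;
    (*used_union)[best_f] = 1;
    (*gini_sum)[best_f] += best_dec;
    *total_dec += best_dec;

    std::vector<int> li, ri;
    for (int i : idx) (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    tree.left[node] = grow(li);
    tree.right[node] = grow(ri);
    return node;
  }
};

static inline int predict_one(const Tree &t, const NumericMatrix &X, int i,
                              int override_f = -1, double override_v = 0) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    double v = (f == override_f) ? override_v : X(i, f);
    node = (v <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int n_classes,
                     int n_trees, int mtry, double lambda, bool scope_forest,
                     int min_node) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<char> usedF(p, 0), used_union(p, 0);
  std::vector<double> gini_sum(p, 0.0);
  double total_dec = 0.0;
  IntegerMatrix inbag(n, n_trees);
  List trees(n_trees);

  for (int k = 0; k < n_trees; ++k) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      idx[i] = rand_int(n);
      inbag(idx[i], k)++;
    }
    std::vector<char> used_tree(p, 0);
    Grower g(X, y, n_classes, mtry, min_node, lambda,
             scope_forest ? &usedF : &used_tree, &used_union, &gini_sum,
             &total_dec);
    g.grow(idx);
    trees[k] = List::create(
      _["feature"] = IntegerVector(g.tree.feature.begin(), g.tree.feature.end()),
      _["threshold"] = NumericVector(g.tree.threshold.begin(), g.tree.threshold.end()),
      _["left"] = IntegerVector(g.tree.left.begin(), g.tree.left.end()),
      _["right"] = IntegerVector(g.tree.right.begin(), g.tree.right.end()),
      _["pred"] = IntegerVector(g.tree.pred.begin(), g.tree.pred.end()));
  }
  return List::create(
    _["trees"] = trees, _["inbag"] = inbag,
    _["gini_sum"] = NumericVector(gini_sum.begin(), gini_sum.end()),
    _["total_decrease"] = total_dec,
    _["used"] = LogicalVector(used_union.begin(), used_union.end()));
}

// Per-gene first and second moments of the per-tree OOB accuracy differences
// (original accuracy minus accuracy after permuting the gene within the
// tree's OOB set; trees not using a gene contribute a zero difference).
// [[Rcpp::export]]
List cpp_forest_perm_importance(List trees, IntegerMatrix inbag,
                                NumericMatrix X, IntegerVector y) {
  const int n = X.nrow(), p = X.ncol(), K = trees.size();
  NumericVector sum(p), sumsq(p);
  for (int k = 0; k < K; ++k) {
    List tl = trees[k];
    Tree t;
    IntegerVector fe = tl["feature"], le = tl["left"], ri = tl["right"],
                  pr = tl["pred"];
    NumericVector th = tl["threshold"];
    t.feature.assign(fe.begin(), fe.end());
    t.threshold.assign(th.begin(), th.end());
    t.left.assign(le.begin(), le.end());
    t.right.assign(ri.begin(), ri.end());
    t.pred.assign(pr.begin(), pr.end());

    std::vector<int> ob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, k) == 0) ob.push_back(i);
    const int m = (int)ob.size();
    if (m == 0) continue;

    double acc0 = 0;
    for (int i : ob) acc0 += (predict_one(t, X, i) == y[i]);
    acc0 /= m;

    std::vector<char> in_tree(p, 0);
    for (int f : t.feature)
      if (f >= 0) in_tree[f] = 1;
    for (int g = 0; g < p; ++g) {
      if (!in_tree[g]) continue;
      std::vector<double> v(m);
      for (int j = 0; j < m; ++j) v[j] = X(ob[j], g);
      for (int j = m - 1; j > 0; --j) std::swap(v[j], v[rand_int(j + 1)]);
      double acc1 = 0;
      for (int j = 0; j < m; ++j)
        acc1 += (predict_one(t, X, ob[j], g, v[j]) == y[ob[j]]);
      acc1 /= m;
      double d = acc0 - acc1;
      sum[g] += d;
      sumsq[g] += d * d;
    }
  }
  return List::create(_["sum"] = sum, _["sumsq"] = sumsq, _["n_trees"] = K);
}
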