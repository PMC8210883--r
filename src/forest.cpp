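#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal classification random forest (CART + bagging) used by the
// cell-state classifier: no forest package is assumed at run time.
// Trees are grown to purity (min_node = 1 by default), splits chosen by
// Gini impurity over `mtry` features sampled without replacement per node.
// All randomness flows through R's RNG so set.seed() governs results.

namespace {

struct Tree {
  // node arrays; feature < 0 marks a leaf whose class is in pred
  std::vector<int> feature;
  std::vector<double> thresh;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<int> pred;
  std::vector<int> used; // distinct features used by internal nodes
};

inline int rand_below(int n) {
  int k = (int)std::floor(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

int majority_class(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;
  return best;
}

// Grow one node; returns node index within tree arrays.
int grow_node(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
              int nclass, std::vector<int> &samp, int lo, int hi,
              int mtry, int min_node, std::vector<int> &featpool) {
  int n = hi - lo;
  std::vector<int> cnt(nclass, 0);
  for (int i = lo; i < hi; ++i) cnt[y[samp[i]]]++;
  int maj = majority_class(cnt);

  int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.thresh.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(maj);

  bool pure = (cnt[maj] == n);
  if (pure || n < 2 * min_node) return node;

  int p = (int)featpool.size();
  double best_score = R_PosInf; // weighted child Gini (lower is better)
  int best_f = -1;
  double best_thr = 0.0;

  // sample mtry distinct features by partial Fisher-Yates
  for (int m = 0; m < mtry; ++m) {
    int j = m + rand_below(p - m);
    std::swap(featpool[m], featpool[j]);
    int f = featpool[m];

    // gather and sort node sample values on feature f
    std::vector<std::pair<double, int> > v(n);
    for (int i = 0; i < n; ++i) {
      int s = samp[lo + i];
      v[i] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) continue; // constant feature

    std::vector<int> lc(nclass, 0), rc(cnt);
    int nl = 0;
    for (int i = 0; i < n - 1; ++i) {
      int cls = v[i].second;
      lc[cls]++; rc[cls]--; nl++;
      if (v[i].first == v[i + 1].first) continue;
      if (nl < min_node || (n - nl) < min_node) continue;
      double gl = 1.0, gr = 1.0;
      for (int c = 0; c < nclass; ++c) {
        double plc = (double)lc[c] / nl;
        double prc = (double)rc[c] / (n - nl);
        gl -= plc * plc;
        gr -= prc * prc;
      }
      double score = (nl * gl + (n - nl) * gr) / n;
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_thr = (v[i].first + v[i + 1].first) / 2.0;
      }
    }
  }

  if (best_f < 0) return node; // no usable split among sampled features

  // partition samp[lo:hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(samp[i], best_f) <= best_thr) std::swap(samp[i], samp[mid++]);
  if (mid == lo || mid == hi) return node; // numeric degeneracy guard

  tree.feature[node] = best_f;
  tree.thresh[node] = best_thr;
  tree.used.push_back(best_f);
  int l = grow_node(tree, X, y, nclass, samp, lo, mid, mtry, min_node, featpool);
  int r = grow_node(tree, X, y, nclass, samp, mid, hi, mtry, min_node, featpool);
  tree.left[node] = l;
  tree.right[node] = r;
  return node;
}

int predict_tree(const Tree &tree, const NumericMatrix &X, int row,
                 const std::vector<int> *perm, int perm_feature) {
  int node = 0;
  while (tree.feature[node] >= 0) {
    int f = tree.feature[node];
    int r = (perm && f == perm_feature) ? (*perm)[row] : row;
    node = (X(r, f) <= tree.thresh[node]) ? tree.left[node] : tree.right[node];
  }
  return tree.pred[node];
}

List serialize_tree(const Tree &tree) {
  return List::create(
      _["feature"] = IntegerVector(tree.feature.begin(), tree.feature.end()),
      _["thresh"] = NumericVector(tree.thresh.begin(), tree.thresh.end()),
      _["left"] = IntegerVector(tree.left.begin(), tree.left.end()),
      _["right"] = IntegerVector(tree.right.begin(), tree.right.end()),
      _["pred"] = IntegerVector(tree.pred.begin(), tree.pred.end()));
}

Tree deserialize_tree(List t) {
  Tree tree;
  IntegerVector f = t["feature"], l = t["left"], r = t["right"], p = t["pred"];
  NumericVector th = t["thresh"];
  tree.feature.assign(f.begin(), f.end());
  tree.thresh.assign(th.begin(), th.end());
  tree.left.assign(l.begin(), l.end());
  tree.right.assign(r.begin(), r.end());
  tree.pred.assign(p.begin(), p.end());
  return tree;
}

} // namespace

// [[Rcpp::export(name = ".rf_grow")]]
List rf_grow(NumericMatrix X, IntegerVector y, int nclass, int ntree,
             int mtry, int min_node, bool importance) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  List trees(ntree);
  IntegerMatrix oob_votes(n, nclass);
  NumericVector imp(p);
  std::vector<int> featpool(p);

  for (int t = 0; t < ntree; ++t) {
    for (int j = 0; j < p; ++j) featpool[j] = j;
    std::vector<int> samp(n);
    std::vector<char> inbag(n, 0);
    for (int i = 0; i < n; ++i) {
      int s = rand_below(n);
      samp[i] = s;
      inbag[s] = 1;
    }
    Tree tree;
    grow_node(tree, X, y, nclass, samp, 0, n, mtry, min_node, featpool);
    trees[t] = serialize_tree(tree);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    int n_oob = (int)oob.size();
    if (n_oob == 0) continue;

    int correct = 0;
    for (int k = 0; k < n_oob; ++k) {
      int cls = predict_tree(tree, X, oob[k], NULL, -1);
      oob_votes(oob[k], cls)++;
      if (cls == y[oob[k]]) correct++;
    }

    if (importance && !tree.used.empty()) {
      std::sort(tree.used.begin(), tree.used.end());
      tree.used.erase(std::unique(tree.used.begin(), tree.used.end()),
                      tree.used.end());
      // permutation map: row -> substitute row, over OOB samples only
      std::vector<int> perm_of(n);
      for (int i = 0; i < n; ++i) perm_of[i] = i;
      std::vector<int> shuffled(oob);
      for (size_t f_i = 0; f_i < tree.used.size(); ++f_i) {
        int f = tree.used[f_i];
        for (int k = n_oob - 1; k > 0; --k)
          std::swap(shuffled[k], shuffled[rand_below(k + 1)]);
        for (int k = 0; k < n_oob; ++k) perm_of[oob[k]] = shuffled[k];
        int correct_perm = 0;
        for (int k = 0; k < n_oob; ++k) {
          int cls = predict_tree(tree, X, oob[k], &perm_of, f);
          if (cls == y[oob[k]]) correct_perm++;
        }
        imp[f] += (double)(correct - correct_perm) / n_oob;
      }
    }
  }
  for (int j = 0; j < p; ++j) imp[j] /= ntree;

  return List::create(_["trees"] = trees, _["oob_votes"] = oob_votes,
                      _["importance"] = imp, _["nclass"] = nclass,
                      _["mtry"] = mtry, _["ntree"] = ntree);
}

// [[Rcpp::export(name = ".rf_votes")]]
IntegerMatrix rf_votes(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int nclass = as<int>(forest["nclass"]);
  int ntree = trees.size(), n = X.nrow();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    Tree tree = deserialize_tree(trees[t]);
    for (int i = 0; i < n; ++i) votes(i, predict_tree(tree, X, i, NULL, -1))++;
  }
  return votes;
}
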