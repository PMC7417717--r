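// Compact random-forest classifier (binary, CART/gini, bootstrap, sqrt-mtry
// by default). Trees are grown to purity subject to a minimum node size, as
// classification forests conventionally are. Uses R's RNG so results are
// reproducible from set.seed() on the R side.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for leaves
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> pred;   // class-1 fraction at the node
};

int grow(const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, std::vector<int>& featpool, Tree& T) {
  const int n = hi - lo;
  int pos = 0;
  for (int i = lo; i < hi; ++i) pos += y[idx[i]];
  const int node = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  T.pred.push_back((double)pos / n);
  if (n <= min_node || pos == 0 || pos == n) return node;

  const int p = X.ncol();
  // partial Fisher-Yates to pick mtry distinct features
  for (int j = 0; j < mtry; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(featpool[j], featpool[k]);
  }

  double best_imp = R_PosInf;
  int best_f = -1; double best_thr = 0.0;
  const double parent_imp = (double)pos * (n - pos) / n;
  std::vector<std::pair<double, int> > vals(n);
  for (int j = 0; j < mtry; ++j) {
    const int f = featpool[j];
    for (int i = 0; i < n; ++i) {
      const int s = idx[lo + i];
      vals[i] = std::make_pair(X(s, f), y[s]);
    }
    std::sort(vals.begin(), vals.end());
    int pos_l = 0;
    for (int k = 1; k < n; ++k) {
      pos_l += vals[k - 1].second;
      if (vals[k].first <= vals[k - 1].first) continue;  // no gap: not a split
      const int nl = k, nr = n - k;
      const int pl = pos_l, pr = pos - pos_l;
      const double imp = (double)pl * (nl - pl) / nl + (double)pr * (nr - pr) / nr;
      if (imp < best_imp - 1e-12) {
        best_imp = imp; best_f = f;
        best_thr = 0.5 * (vals[k - 1].first + vals[k].first);
      }
    }
  }
  if (best_f < 0 || best_imp >= parent_imp - 1e-12) return node;

  const int col = best_f;
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], col) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // degenerate (shouldn't happen)
  T.feat[node] = best_f; T.thr[node] = best_thr;
  const int l = grow(X, y, idx, lo, mid, mtry, min_node, featpool, T);
  T.left[node] = l;
  const int r = grow(X, y, idx, mid, hi, mtry, min_node, featpool, T);
  T.right[node] = r;
  return node;
}

double predict_one(const Tree& T, const NumericMatrix& X, int row) {
  int node = 0;
  while (T.feat[node] >= 0)
    node = (X(row, T.feat[node]) <= T.thr[node]) ? T.left[node] : T.right[node];
  return T.pred[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_predict")]]
NumericVector rf_fit_predict(NumericMatrix Xtrain, IntegerVector ytrain,
                             NumericMatrix Xtest,
                             int n_trees, int mtry, int min_node) {
  const int n = Xtrain.nrow();
  if (n == 0 || Xtest.ncol() != Xtrain.ncol())
    stop("bad training/test dimensions");
  if (mtry < 1 || mtry > Xtrain.ncol()) stop("bad mtry");
  NumericVector score(Xtest.nrow());
  std::vector<int> idx(n), featpool(Xtrain.ncol());
  GetRNGstate();
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) {               // bootstrap sample
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
    }
    for (int j = 0; j < (int)featpool.size(); ++j) featpool[j] = j;
    Tree T;
    grow(Xtrain, ytrain, idx, 0, n, mtry, min_node, featpool, T);
    for (int i = 0; i < Xtest.nrow(); ++i)
      score[i] += predict_one(T, Xtest, i);
  }
  PutRNGstate();
  return score / (double)n_trees;
}
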