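// Random-forest classifier (binary, CART trees, Gini split criterion,
// bootstrap resampling, mtry feature subsampling, impurity importance).
// Mirrors the classical randomForest defaults: trees grown to purity
// (nodesize 1), mtry = floor(sqrt(p)).  Uses R's RNG (unif_rand) so results
// are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1 for leaf
  double threshold = 0.0; // go left if x <= threshold
  int left = -1, right = -1;
  double prob1 = 0.0;     // class-1 fraction (leaves)
};

inline double gini(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

inline int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

}  // namespace

// [[Rcpp::export]]
List rf_fit_predict_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
                        int n_trees, int mtry, int min_node) {
  const int n = X.nrow(), p = X.ncol(), nt = Xtest.nrow();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  NumericVector prob(nt, 0.0), importance(p, 0.0);

  std::vector<int> feat_pool(p);
  std::vector<int> order_buf(n);

  for (int t = 0; t < n_trees; ++t) {
    // bootstrap sample
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);

    std::vector<Node> tree;
    tree.reserve(2 * n);
    // stack of (node id, member index range in `members`)
    std::vector<int> members = idx;
    struct Job { int node, lo, hi; };
    std::vector<Job> stack;
    tree.push_back(Node());
    stack.push_back({0, 0, n});

    while (!stack.empty()) {
      Job jb = stack.back();
      stack.pop_back();
      const int lo = jb.lo, hi = jb.hi, nn = hi - lo;
      int n1 = 0;
      for (int k = lo; k < hi; ++k) n1 += y[members[k]];
      Node& nd0 = tree[jb.node];
      nd0.prob1 = nn > 0 ? (double)n1 / nn : 0.0;
      if (nn < std::max(2, min_node + 1) || n1 == 0 || n1 == nn) continue;

      // sample mtry features without replacement
      for (int f = 0; f < p; ++f) feat_pool[f] = f;
      double best_dec = 1e-12;
      int best_f = -1;
      double best_thr = 0.0;
      const double g_parent = gini(n1, nn) * nn;
      for (int s = 0; s < mtry; ++s) {
        int pick = s + rand_int(p - s);
        std::swap(feat_pool[s], feat_pool[pick]);
        const int f = feat_pool[s];
        // sort node members by feature value
        std::vector<int>& ord = order_buf;
        ord.assign(members.begin() + lo, members.begin() + hi);
        std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
          return X(a, f) < X(b, f);
        });
        int l1 = 0;
        for (int k = 0; k < nn - 1; ++k) {
          l1 += y[ord[k]];
          if (X(ord[k], f) == X(ord[k + 1], f)) continue;
          const int nl = k + 1, nr = nn - nl;
          double dec = g_parent - gini(l1, nl) * nl - gini(n1 - l1, nr) * nr;
          if (dec > best_dec) {
            best_dec = dec;
            best_f = f;
            best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
          }
        }
      }
      if (best_f < 0) continue;

      // partition members (stable)
      std::vector<int> left_m, right_m;
      left_m.reserve(nn); right_m.reserve(nn);
      for (int k = lo; k < hi; ++k) {
        if (X(members[k], best_f) <= best_thr) left_m.push_back(members[k]);
        else right_m.push_back(members[k]);
      }
      std::copy(left_m.begin(), left_m.end(), members.begin() + lo);
      std::copy(right_m.begin(), right_m.end(),
                members.begin() + lo + left_m.size());

      const int li = (int)tree.size(), rix = li + 1;
      tree.push_back(Node());
      tree.push_back(Node());
      Node& nd = tree[jb.node];
      nd.feature = best_f;
      nd.threshold = best_thr;
      nd.left = li;
      nd.right = rix;
      importance[best_f] += best_dec;
      stack.push_back({li, lo, lo + (int)left_m.size()});
      stack.push_back({rix, lo + (int)left_m.size(), hi});
    }

    // predict test rows
    for (int i = 0; i < nt; ++i) {
      int node = 0;
      while (tree[node].feature >= 0) {
        node = Xtest(i, tree[node].feature) <= tree[node].threshold
                   ? tree[node].left
                   : tree[node].right;
      }
      prob[i] += tree[node].prob1;
    }
  }
  for (int i = 0; i < nt; ++i) prob[i] /= n_trees;
  for (int f = 0; f < p; ++f) importance[f] /= n_trees;
  return List::create(_["prob"] = prob, _["importance"] = importance);
}
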