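// Surrogate-split regression trees with node-risk importance.
//
// Node risk = node MSE weighted by the node's training-sample probability,
// i.e. risk = (sum of squared deviations at node) / n_root.  Split quality is
// the parent risk minus the summed risk of its two children.  Per-feature
// importance sums risk reductions over all splits (primary and surrogate) at
// every branch node and divides by the branch-node count.
//
// Growth keeps, for every node, its rows sorted by each feature (built once
// from a per-call presort, maintained by stable partition), so both the
// primary split search and the surrogate-agreement search are linear scans.
#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>
using namespace Rcpp;

namespace {

struct Surrogate {
  int feature;       // 0-based
  double threshold;
  double lambda;     // predictive measure of association
  double rr;         // risk reduction of the surrogate's own partition
};

struct Node {
  int feature = -1;  // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int n = 0;
  double prob = 0.0, mse = 0.0, risk = 0.0, pred = 0.0;
  double rr = 0.0;   // primary split risk reduction
  std::vector<Surrogate> surr;
};

struct Tree {
  std::vector<Node> nodes;
  int n_branch = 0;
};

// Rows of one node sorted by every feature: lists[f * n + i] is the row id
// of the i-th smallest value of feature f among the node's rows.
struct NodeWork {
  int node;
  int n;
  std::vector<int> lists;
};

Tree grow_tree(const NumericMatrix& X, const NumericVector& y,
               NodeWork root, int min_leaf, int mtry, int max_surr,
               std::mt19937& rng) {
  const int p = X.ncol();
  const int n_root = root.n;
  Tree tree;
  std::vector<int> feat_pool(p);
  for (int f = 0; f < p; ++f) feat_pool[f] = f;

  std::vector<NodeWork> stack;
  tree.nodes.emplace_back();
  root.node = 0;
  stack.push_back(std::move(root));

  while (!stack.empty()) {
    NodeWork it = std::move(stack.back());
    stack.pop_back();
    const int n = it.n;
    const int* lst0 = it.lists.data();  // feature-0 block (any order works)
    double sum = 0.0, sq = 0.0;
    for (int i = 0; i < n; ++i) {
      const double yi = y[lst0[i]];
      sum += yi;
      sq += yi * yi;
    }
    double sse = sq - sum * sum / n;
    if (sse < 0.0) sse = 0.0;
    Node& nd0 = tree.nodes[it.node];
    nd0.n = n;
    nd0.pred = sum / n;
    nd0.prob = n / (double)n_root;
    nd0.mse = sse / n;
    nd0.risk = sse / n_root;
    if (n < 2 * min_leaf || sse <= 0.0) continue;  // leaf

    // candidate features: mtry-subset without replacement, scanned in
    // ascending index order so ties break to the lowest feature index
    int m = std::min(mtry, p);
    if (m < p) {
      for (int i = 0; i < m; ++i) {
        std::uniform_int_distribution<int> d(i, p - 1);
        std::swap(feat_pool[i], feat_pool[d(rng)]);
      }
      std::sort(feat_pool.begin(), feat_pool.begin() + m);
    }
    // strict improvement with a relative tolerance: mathematically tied
    // gains (identical partitions reached through different features)
    // must resolve to the lowest feature index / lowest threshold no
    // matter the floating-point summation order
    const double gain_tol = 1e-12 * sse;
    double best_gain = 0.0;
    int best_f = -1;
    double best_thr = 0.0;
    for (int ci = 0; ci < m; ++ci) {
      const int f = (m < p) ? feat_pool[ci] : ci;
      const int* lst = it.lists.data() + (size_t)f * n;
      const double* xcol = &X(0, f);
      double sumL = 0.0, sqL = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        const double yi = y[lst[i]];
        sumL += yi;
        sqL += yi * yi;
        if (xcol[lst[i]] >= xcol[lst[i + 1]]) continue;  // not a boundary
        const int nL = i + 1, nR = n - nL;
        if (nL < min_leaf || nR < min_leaf) continue;
        const double sseL = sqL - sumL * sumL / nL;
        const double sumR = sum - sumL, sqR = sq - sqL;
        const double sseR = sqR - sumR * sumR / nR;
        const double gain = sse - sseL - sseR;
        if (gain > best_gain + gain_tol) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (xcol[lst[i]] + xcol[lst[i + 1]]);
        }
      }
    }
    if (m < p) std::sort(feat_pool.begin(), feat_pool.end());
    if (best_f < 0) continue;  // no positive-reduction split: leaf

    Node& nd = tree.nodes[it.node];
    nd.feature = best_f;
    nd.threshold = best_thr;
    nd.rr = best_gain / n_root;
    ++tree.n_branch;

    // routing of the primary split (duplicated bootstrap rows share a row
    // id and always route together)
    const double* xprim = &X(0, best_f);
    const double thr = best_thr;
    int nL = 0;
    {
      const int* lst = it.lists.data();
      for (int i = 0; i < n; ++i) nL += (xprim[lst[i]] < thr) ? 1 : 0;
    }
    const int nR = n - nL;
    const double minp = std::min(nL, nR) / (double)n;

    // surrogates: per other feature, the left_if_less threshold with
    // maximal agreement with the primary partition; keep lambda > 0
    if (max_surr > 0 && minp > 0.0) {
      nd.surr.clear();
      for (int f = 0; f < p; ++f) {
        if (f == best_f) continue;
        const int* lst = it.lists.data() + (size_t)f * n;
        const double* xcol = &X(0, f);
        int bestAgree = -1, bestCut = -1;
        int prefL = 0;
        for (int i = 0; i < n - 1; ++i) {
          prefL += (xprim[lst[i]] < thr) ? 1 : 0;
          if (xcol[lst[i]] >= xcol[lst[i + 1]]) continue;
          // first i+1 rows routed left by surrogate:
          // agreements = prefL + right-labelled rows after i
          const int agree = prefL + (nR - ((i + 1) - prefL));
          if (agree > bestAgree) {
            bestAgree = agree;
            bestCut = i;
          }
        }
        if (bestCut < 0) continue;
        const double p_agree = bestAgree / (double)n;
        const double lambda = (minp - (1.0 - p_agree)) / minp;
        if (lambda <= 0.0) continue;
        double sumL = 0.0, sqL = 0.0;
        for (int i = 0; i <= bestCut; ++i) {
          const double yi = y[lst[i]];
          sumL += yi;
          sqL += yi * yi;
        }
        const int cL = bestCut + 1, cR = n - cL;
        const double sseL = sqL - sumL * sumL / cL;
        const double sumR = sum - sumL, sqR = sq - sqL;
        const double sseR = sqR - sumR * sumR / cR;
        double gain = sse - sseL - sseR;
        if (gain < 0.0) gain = 0.0;  // fp guard
        Surrogate s;
        s.feature = f;
        s.threshold = 0.5 * (xcol[lst[bestCut]] + xcol[lst[bestCut + 1]]);
        s.lambda = lambda;
        s.rr = gain / n_root;
        nd.surr.push_back(s);
      }
      // lambda ties are common (agreement counts are integers); break
      // them by own risk reduction so truncation to max_surr does not
      // systematically favour low feature indices
      std::stable_sort(nd.surr.begin(), nd.surr.end(),
                       [](const Surrogate& a, const Surrogate& b) {
                         if (a.lambda != b.lambda)
                           return a.lambda > b.lambda;
                         if (a.rr != b.rr) return a.rr > b.rr;
                         return a.feature < b.feature;
                       });
      if ((int)nd.surr.size() > max_surr) nd.surr.resize(max_surr);
    }

    // stable partition of every feature's sorted list
    NodeWork wl, wr;
    wl.n = nL;
    wr.n = nR;
    wl.lists.resize((size_t)p * nL);
    wr.lists.resize((size_t)p * nR);
    for (int f = 0; f < p; ++f) {
      const int* src = it.lists.data() + (size_t)f * n;
      int* dl = wl.lists.data() + (size_t)f * nL;
      int* dr = wr.lists.data() + (size_t)f * nR;
      for (int i = 0; i < n; ++i) {
        const int r = src[i];
        if (xprim[r] < thr)
          *dl++ = r;
        else
          *dr++ = r;
      }
    }
    const int li = (int)tree.nodes.size();
    tree.nodes.emplace_back();
    const int ri = (int)tree.nodes.size();
    tree.nodes.emplace_back();
    tree.nodes[it.node].left = li;
    tree.nodes[it.node].right = ri;
    wl.node = li;
    wr.node = ri;
    stack.push_back(std::move(wr));
    stack.push_back(std::move(wl));  // left processed (and numbered) first
  }
  return tree;
}

void tree_importance(const Tree& t, std::vector<double>& imp) {
  std::fill(imp.begin(), imp.end(), 0.0);
  if (t.n_branch == 0) return;
  for (const Node& nd : t.nodes) {
    if (nd.feature < 0) continue;
    imp[nd.feature] += nd.rr;
    for (const Surrogate& s : nd.surr) imp[s.feature] += s.rr;
  }
  for (double& v : imp) v /= t.n_branch;
}

double predict_row(const Tree& t, const NumericMatrix& X, int row) {
  int i = 0;
  while (t.nodes[i].feature >= 0) {
    i = (X(row, t.nodes[i].feature) < t.nodes[i].threshold)
            ? t.nodes[i].left
            : t.nodes[i].right;
  }
  return t.nodes[i].pred;
}

List tree_to_list(const Tree& t) {
  const int m = (int)t.nodes.size();
  IntegerVector feature(m), left(m), right(m), n(m);
  NumericVector threshold(m), prob(m), mse(m), risk(m), pred(m), rr(m);
  List surr(m);
  for (int i = 0; i < m; ++i) {
    const Node& nd = t.nodes[i];
    feature[i] = nd.feature;  // 0-based, -1 leaf
    left[i] = nd.left;
    right[i] = nd.right;
    n[i] = nd.n;
    threshold[i] = nd.threshold;
    prob[i] = nd.prob;
    mse[i] = nd.mse;
    risk[i] = nd.risk;
    pred[i] = nd.pred;
    rr[i] = nd.rr;
    const int k = (int)nd.surr.size();
    NumericMatrix sm(k, 4);
    for (int j = 0; j < k; ++j) {
      sm(j, 0) = nd.surr[j].feature;  // 0-based
      sm(j, 1) = nd.surr[j].threshold;
      sm(j, 2) = nd.surr[j].lambda;
      sm(j, 3) = nd.surr[j].rr;
    }
    surr[i] = sm;
  }
  return List::create(
      _["feature"] = feature, _["threshold"] = threshold, _["left"] = left,
      _["right"] = right, _["n"] = n, _["prob"] = prob, _["mse"] = mse,
      _["risk"] = risk, _["pred"] = pred, _["risk_reduction"] = rr,
      _["surrogates"] = surr, _["n_branch"] = t.n_branch);
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, NumericVector y, int n_trees,
                     bool bootstrap, int mtry, int min_leaf,
                     int max_surrogates, int seed, bool return_trees,
                     Nullable<NumericMatrix> Xtest = R_NilValue) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y have mismatched lengths");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (n < 1) stop("empty training set");

  // presort every feature once per call; per-tree sorted lists are built
  // from these orders with bootstrap multiplicities
  std::vector<int> presort((size_t)p * n);
  for (int f = 0; f < p; ++f) {
    int* o = presort.data() + (size_t)f * n;
    const double* xcol = &X(0, f);
    for (int i = 0; i < n; ++i) o[i] = i;
    std::stable_sort(o, o + n,
                     [&](int a, int b) { return xcol[a] < xcol[b]; });
  }

  NumericVector imp_mean(p);
  std::vector<double> imp(p);
  NumericMatrix Xt;
  bool has_test = Xtest.isNotNull();
  NumericVector test_pred;
  if (has_test) {
    Xt = NumericMatrix(Xtest);
    if (Xt.ncol() != p) stop("test matrix column count mismatch");
    test_pred = NumericVector(Xt.nrow());
  }
  List trees(return_trees ? n_trees : 0);
  std::vector<int> mult(n);
  for (int t = 0; t < n_trees; ++t) {
    std::seed_seq sq{seed, t};
    std::mt19937 rng(sq);
    NodeWork root;
    if (bootstrap) {
      std::fill(mult.begin(), mult.end(), 0);
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int i = 0; i < n; ++i) ++mult[d(rng)];
    } else {
      std::fill(mult.begin(), mult.end(), 1);
    }
    root.n = n;
    root.lists.resize((size_t)p * n);
    for (int f = 0; f < p; ++f) {
      const int* o = presort.data() + (size_t)f * n;
      int* dst = root.lists.data() + (size_t)f * n;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < mult[o[i]]; ++k) *dst++ = o[i];
    }
    Tree tr = grow_tree(X, y, std::move(root), min_leaf, mtry,
                        max_surrogates, rng);
    tree_importance(tr, imp);
    for (int f = 0; f < p; ++f) imp_mean[f] += imp[f];
    if (has_test) {
      for (int i = 0; i < Xt.nrow(); ++i)
        test_pred[i] += predict_row(tr, Xt, i);
    }
    if (return_trees) {
      List tl = tree_to_list(tr);
      tl["importance"] = NumericVector(imp.begin(), imp.end());
      trees[t] = tl;
    }
  }
  for (int f = 0; f < p; ++f) imp_mean[f] /= n_trees;
  if (has_test)
    for (int i = 0; i < test_pred.size(); ++i) test_pred[i] /= n_trees;
  List out = List::create(_["importance"] = imp_mean,
                          _["n_trees"] = n_trees);
  if (has_test) out["test_pred"] = test_pred;
  if (return_trees) out["trees"] = trees;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               NumericVector pred, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    int i = 0;
    while (feature[i] >= 0)
      i = (X(r, feature[i]) < threshold[i]) ? left[i] : right[i];
    out[r] = pred[i];
  }
  return out;
}
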