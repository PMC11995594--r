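// Bagged CART classification forest with Gini splitting, per-node feature
// subsampling (mtry) and Gini impurity-decrease importance. Implemented here
// because no random-forest package is available in the target environment;
// hyperparameters follow the pipeline's fixed settings (500 trees, minimum
// node size 1, tuned mtry). Uses R's RNG so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> var, left, right;
  std::vector<double> split, pred;
};

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry > p) mtry = p;
  List trees(ntree);
  NumericVector importance(p);

  std::vector<int> boot(n);
  std::vector<int> ylab(n);
  // per-variable position lists sorted by value; all share node segments
  std::vector<std::vector<int>> sorted(p, std::vector<int>(n));
  std::vector<int> tmpL(n), tmpR(n);
  std::vector<char> goes_left(n);

  for (int tr = 0; tr < ntree; ++tr) {
    for (int i = 0; i < n; ++i) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      boot[i] = k;
      ylab[i] = y[k];
    }
    for (int j = 0; j < p; ++j) {
      std::vector<int>& s = sorted[j];
      for (int i = 0; i < n; ++i) s[i] = i;
      const double* col = &X(0, j);
      std::sort(s.begin(), s.end(), [&](int a, int b) {
        return col[boot[a]] < col[boot[b]];
      });
    }
    TreeBuf tb;
    // stack of (lo, hi, node_id)
    std::vector<std::array<int, 3>> stack;
    auto new_node = [&]() {
      tb.var.push_back(-1); tb.split.push_back(0.0);
      tb.left.push_back(-1); tb.right.push_back(-1); tb.pred.push_back(0.0);
      return (int)tb.var.size() - 1;
    };
    int root = new_node();
    stack.push_back({0, n, root});
    std::vector<int> vars(p);

    while (!stack.empty()) {
      auto nd = stack.back(); stack.pop_back();
      const int lo = nd[0], hi = nd[1], id = nd[2], cnt = hi - lo;
      int n1 = 0;
      for (int i = lo; i < hi; ++i) n1 += ylab[sorted[0][i]];
      tb.pred[id] = (double)n1 / cnt;
      if (n1 == 0 || n1 == cnt || cnt < 2 * std::max(1, min_node)) continue;

      const double ssq_parent = ((double)n1 * n1 + (double)(cnt - n1) * (cnt - n1)) / cnt;
      double best_gain = 0.0, best_thr = 0.0;
      int best_var = -1, best_nl = 0;

      // sample mtry variables without replacement (partial Fisher-Yates)
      for (int j = 0; j < p; ++j) vars[j] = j;
      for (int m = 0; m < mtry; ++m) {
        int r = m + (int)(unif_rand() * (p - m));
        if (r >= p) r = p - 1;
        std::swap(vars[m], vars[r]);
        const int j = vars[m];
        const std::vector<int>& s = sorted[j];
        const double* col = &X(0, j);
        int nl = 0, n1l = 0;
        for (int i = lo; i < hi - 1; ++i) {
          const int pos = s[i];
          ++nl; n1l += ylab[pos];
          const double xv = col[boot[pos]], xn = col[boot[s[i + 1]]];
          if (xn <= xv) continue;  // no split between tied values
          const int nr = cnt - nl, n1r = n1 - n1l;
          const double ssq =
            ((double)n1l * n1l + (double)(nl - n1l) * (nl - n1l)) / nl +
            ((double)n1r * n1r + (double)(nr - n1r) * (nr - n1r)) / nr;
          const double gain = ssq - ssq_parent;
          if (gain > best_gain + 1e-12 &&
              nl >= std::max(1, min_node) && nr >= std::max(1, min_node)) {
            best_gain = gain; best_var = j;
            best_thr = 0.5 * (xv + xn); best_nl = nl;
          }
        }
      }
      if (best_var < 0) continue;  // no valid impurity-reducing split

      importance[best_var] += best_gain / n;
      const double* bcol = &X(0, best_var);
      for (int i = lo; i < hi; ++i) {
        const int pos = sorted[best_var][i];
        goes_left[pos] = bcol[boot[pos]] <= best_thr;
      }
      // stable partition of every variable's segment
      for (int j = 0; j < p; ++j) {
        std::vector<int>& s = sorted[j];
        int a = 0, b = 0;
        for (int i = lo; i < hi; ++i) {
          const int pos = s[i];
          if (goes_left[pos]) tmpL[a++] = pos; else tmpR[b++] = pos;
        }
        std::copy(tmpL.begin(), tmpL.begin() + a, s.begin() + lo);
        std::copy(tmpR.begin(), tmpR.begin() + b, s.begin() + lo + a);
      }
      const int lid = new_node(), rid = new_node();
      tb.var[id] = best_var; tb.split[id] = best_thr;
      tb.left[id] = lid; tb.right[id] = rid;
      stack.push_back({lo, lo + best_nl, lid});
      stack.push_back({lo + best_nl, hi, rid});
    }
    trees[tr] = List::create(
      _["var"] = IntegerVector(tb.var.begin(), tb.var.end()),
      _["split"] = NumericVector(tb.split.begin(), tb.split.end()),
      _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
      _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
      _["pred"] = NumericVector(tb.pred.begin(), tb.pred.end()));
  }
  for (int j = 0; j < p; ++j) importance[j] /= ntree;
  return List::create(_["trees"] = trees, _["importance"] = importance);
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int tr = 0; tr < ntree; ++tr) {
    List t = trees[tr];
    IntegerVector var = t["var"], left = t["left"], right = t["right"];
    NumericVector split = t["split"], pred = t["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (var[node] >= 0)
        node = X(i, var[node]) <= split[node] ? left[node] : right[node];
      out[i] += pred[node];
    }
  }
  return out / (double)ntree;
}
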