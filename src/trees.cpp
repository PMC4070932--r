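// Minimal CART regression-tree engine backing the boosted_trees and
// random_forest backends. Squared-error splits, per-node random feature
// subsetting (mtry), bootstrap handled by passing row indices. All
// randomness flows through R's RNG (unif_rand), so results are a pure
// function of set.seed() state.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct FlatTree {
  std::vector<int> var;        // split variable (0-based), -1 for leaf
  std::vector<double> split;   // threshold: go left when x < split
  std::vector<int> left, right;
  std::vector<double> value;   // leaf mean (node mean for internals too)
};

// Sample m of p feature indices without replacement via partial Fisher-Yates.
static void sample_features(int p, int m, std::vector<int>& out) {
  std::vector<int> pool(p);
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.clear();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out.push_back(pool[i]);
  }
}

static int build_node(const NumericMatrix& X, const NumericVector& y,
                      std::vector<int>& rows, int depth,
                      int max_depth, int min_node, int mtry, FlatTree& tr) {
  const int n = rows.size();
  double sum = 0.0;
  for (int i = 0; i < n; ++i) sum += y[rows[i]];
  const double mean = sum / n;

  int id = tr.var.size();
  tr.var.push_back(-1); tr.split.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1);
  tr.value.push_back(mean);

  bool constant = true;
  for (int i = 1; i < n && constant; ++i)
    if (y[rows[i]] != y[rows[0]]) constant = false;
  if (depth >= max_depth || n < 2 * min_node || constant) return id;

  const int p = X.ncol();
  std::vector<int> feats;
  sample_features(p, std::min(mtry, p), feats);

  double base = sum * sum / n;
  double best_gain = 1e-12;
  int best_var = -1, best_pos = -1;
  std::vector<int> ord(n);
  std::vector<int> best_ord;
  std::vector<double> xs(n);

  for (size_t f = 0; f < feats.size(); ++f) {
    const int v = feats[f];
    for (int i = 0; i < n; ++i) { ord[i] = rows[i]; }
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, v) < X(b, v); });
    for (int i = 0; i < n; ++i) xs[i] = X(ord[i], v);
    double sl = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      sl += y[ord[i]];
      const int nl = i + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      if (xs[i + 1] <= xs[i]) continue;   // need distinct values to cut
      const double sr = sum - sl;
      const double gain = sl * sl / nl + sr * sr / nr - base;
      if (gain > best_gain) {
        best_gain = gain; best_var = v; best_pos = i;
        best_ord = ord;
      }
    }
  }
  if (best_var < 0) return id;

  const double thr = (X(best_ord[best_pos], best_var) +
                      X(best_ord[best_pos + 1], best_var)) / 2.0;
  std::vector<int> lrows(best_ord.begin(), best_ord.begin() + best_pos + 1);
  std::vector<int> rrows(best_ord.begin() + best_pos + 1, best_ord.end());

  tr.var[id] = best_var;
  tr.split[id] = thr;
  tr.left[id] = build_node(X, y, lrows, depth + 1, max_depth, min_node, mtry, tr);
  tr.right[id] = build_node(X, y, rrows, depth + 1, max_depth, min_node, mtry, tr);
  return id;
}

static List tree_to_list(const FlatTree& tr) {
  return List::create(_["var"] = wrap(tr.var), _["split"] = wrap(tr.split),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["value"] = wrap(tr.value));
}

// [[Rcpp::export]]
List cpp_tree_fit(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int max_depth, int min_node, int mtry) {
  std::vector<int> rv(rows.begin(), rows.end());
  FlatTree tr;
  build_node(X, y, rv, 0, max_depth, min_node, mtry, tr);
  return tree_to_list(tr);
}

static int descend(const IntegerVector& var, const NumericVector& split,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericMatrix& X, int i) {
  int node = 0;
  while (var[node] >= 0)
    node = (X(i, var[node]) < split[node]) ? left[node] : right[node];
  return node;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector split = tree["split"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = value[descend(var, split, left, right, X, i)];
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
  NumericVector split = tree["split"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = descend(var, split, left, right, X, i);
  return out;
}

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, NumericVector y, int n_trees,
                    int max_depth, int min_node, int mtry,
                    double sample_frac, bool replace) {
  const int n = X.nrow();
  const int m = std::max(1, (int)std::lround(sample_frac * n));
  List forest(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> rows(m);
    if (replace) {
      for (int i = 0; i < m; ++i) {
        int j = (int)(unif_rand() * n);
        rows[i] = j >= n ? n - 1 : j;
      }
    } else {
      std::vector<int> pool(n);
      for (int i = 0; i < n; ++i) pool[i] = i;
      for (int i = 0; i < m; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        if (j >= n) j = n - 1;
        std::swap(pool[i], pool[j]);
        rows[i] = pool[i];
      }
    }
    FlatTree tr;
    build_node(X, y, rows, 0, max_depth, min_node, mtry, tr);
    forest[t] = tree_to_list(tr);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < forest.size(); ++t) {
    List tree = forest[t];
    IntegerVector var = tree["var"], left = tree["left"], right = tree["right"];
    NumericVector split = tree["split"], value = tree["value"];
    for (int i = 0; i < n; ++i)
      out[i] += value[descend(var, split, left, right, X, i)];
  }
  const double k = forest.size();
  for (int i = 0; i < n; ++i) out[i] /= k;
  return out;
}
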