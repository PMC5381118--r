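#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Deterministic counter-based RNG (splitmix64) so forests are reproducible
// from one root seed regardless of R's RNG state or evaluation order.
struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct SplitResult {
  bool valid;
  int feature;       // 0-based
  double threshold;
  double ssr;
  double left_mean;
  double right_mean;
};

// Exhaustive SSR minimisation over the given candidate features and all
// midpoints between consecutive distinct sorted values. Ties broken by lowest
// feature index, then smallest threshold (strict improvement required).
static SplitResult best_split_impl(const NumericMatrix& X, const NumericVector& y,
                                   const std::vector<int>& rows,
                                   const std::vector<int>& candidates) {
  SplitResult best{false, -1, 0.0, 0.0, 0.0, 0.0};
  const int n = (int)rows.size();
  if (n < 2) return best;

  // tie tolerance scaled by the node's total sum of squares: mathematically
  // tied SSRs (up to rounding) resolve to the first candidate in scan order,
  // i.e. lowest feature index then smallest threshold
  double ysum = 0.0, ysq = 0.0;
  for (int r : rows) { ysum += y[r]; ysq += y[r] * y[r]; }
  const double tss = std::max(ysq - ysum * ysum / n, 0.0);
  const double eps = 1e-10 * tss + 1e-12;

  std::vector<std::pair<double,double> > vy(n); // (feature value, target)
  for (int ci : candidates) {
    for (int i = 0; i < n; ++i) {
      vy[i].first = X(rows[i], ci);
      vy[i].second = y[rows[i]];
    }
    std::sort(vy.begin(), vy.end());
    if (vy.front().first == vy.back().first) continue; // constant feature

    double tot_sum = 0.0;
    for (int i = 0; i < n; ++i) tot_sum += vy[i].second;
    double tot_sq = 0.0;
    for (int i = 0; i < n; ++i) tot_sq += vy[i].second * vy[i].second;

    double lsum = 0.0, lsq = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      lsum += vy[i].second;
      lsq  += vy[i].second * vy[i].second;
      if (vy[i].first == vy[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      const double rsum = tot_sum - lsum, rsq = tot_sq - lsq;
      double ssr = (lsq - lsum * lsum / nl) + (rsq - rsum * rsum / nr);
      if (ssr < 0.0) ssr = 0.0; // guard against rounding
      if (!best.valid || ssr < best.ssr - eps) {
        best.valid = true;
        best.feature = ci;
        best.threshold = (vy[i].first + vy[i + 1].first) / 2.0;
        best.ssr = ssr;
        best.left_mean = lsum / nl;
        best.right_mean = rsum / nr;
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, NumericVector y, IntegerVector candidates) {
  std::vector<int> rows(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) rows[i] = i;
  std::vector<int> cand(candidates.begin(), candidates.end());
  SplitResult r = best_split_impl(X, y, rows, cand);
  return List::create(_["valid"] = r.valid,
                      _["feature"] = r.feature + 1, // 1-based for R
                      _["threshold"] = r.threshold,
                      _["ssr"] = r.ssr,
                      _["left_mean"] = r.left_mean,
                      _["right_mean"] = r.right_mean);
}

struct TreeBuffers {
  std::vector<int> feature;     // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right; // 0-based node ids, -1 for leaf
  std::vector<double> value;    // leaf prediction (node mean)
};

static bool is_constant(const NumericVector& y, const std::vector<int>& rows) {
  for (size_t i = 1; i < rows.size(); ++i)
    if (y[rows[i]] != y[rows[0]]) return false;
  return true;
}

// draw `mtry` distinct feature indices from 0..p-1 (partial Fisher-Yates)
static std::vector<int> draw_candidates(int p, int mtry, SplitMix64& rng) {
  std::vector<int> idx(p);
  for (int i = 0; i < p; ++i) idx[i] = i;
  for (int i = 0; i < mtry; ++i) {
    int j = i + rng.below(p - i);
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> out(idx.begin(), idx.begin() + mtry);
  std::sort(out.begin(), out.end());
  return out;
}

static int grow_node(const NumericMatrix& X, const NumericVector& y,
                     std::vector<int>& rows, int mtry, int min_leaf,
                     SplitMix64& rng, TreeBuffers& t) {
  const int n = (int)rows.size();
  double mean = 0.0;
  for (int r : rows) mean += y[r];
  mean /= n;

  const int id = (int)t.feature.size();
  t.feature.push_back(-1);
  t.threshold.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.value.push_back(mean);

  if (n < 2 * min_leaf || is_constant(y, rows)) return id;

  std::vector<int> cand = draw_candidates((int)X.ncol(), mtry, rng);
  SplitResult s = best_split_impl(X, y, rows, cand);
  if (!s.valid) return id;

  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int r : rows) {
    if (X(r, s.feature) <= s.threshold) lrows.push_back(r);
    else rrows.push_back(r);
  }
  if (lrows.empty() || rrows.empty()) return id; // degenerate, keep as leaf

  t.feature[id] = s.feature;
  t.threshold[id] = s.threshold;
  rows.clear(); rows.shrink_to_fit();
  t.left[id] = grow_node(X, y, lrows, mtry, min_leaf, rng, t);
  t.right[id] = grow_node(X, y, rrows, mtry, min_leaf, rng, t);
  return id;
}

static List tree_to_list(const TreeBuffers& t) {
  return List::create(_["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
                      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["value"] = NumericVector(t.value.begin(), t.value.end()));
}

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                    int min_leaf, double seed, bool bootstrap) {
  const int n = X.nrow();
  List trees(n_trees);
  List bags(n_trees);
  for (int ti = 0; ti < n_trees; ++ti) {
    // per-tree substream keyed on (root seed, tree index)
    SplitMix64 rng(((uint64_t)seed) * 0x100000001ULL + (uint64_t)ti + 1ULL);
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = rng.below(n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    IntegerVector bag(rows.size());
    for (size_t i = 0; i < rows.size(); ++i) bag[i] = rows[i] + 1;

    TreeBuffers t;
    std::vector<int> work = rows;
    grow_node(X, y, work, mtry, min_leaf, rng, t);
    trees[ti] = tree_to_list(t);
    bags[ti] = bag;
  }
  return List::create(_["trees"] = trees, _["bags"] = bags);
}

static double predict_one(const List& tree, const NumericMatrix& X, int row) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector value = tree["value"];
  int node = 0;
  while (feature[node] >= 0) {
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  }
  return value[node];
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X, NumericVector weights) {
  const int n = X.nrow();
  const int T = trees.size();
  NumericVector out(n);
  for (int ti = 0; ti < T; ++ti) {
    List tree = trees[ti];
    const double w = weights[ti];
    if (w == 0.0) continue;
    for (int i = 0; i < n; ++i) out[i] += w * predict_one(tree, X, i);
  }
  return out;
}
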