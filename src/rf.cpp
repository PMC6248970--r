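#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Compact CART random forest for binary classification, used both by the
// wrapper feature-subset search (many small fits) and the final model.
// Self-contained RNG (xorshift-based splitmix/mt19937) so results are
// reproducible for a given seed regardless of R's RNG state.

namespace {

struct Node {
  int feat;      // split feature (column), -1 for leaf
  double thr;    // go left if x <= thr
  int left, right;
  int pred;      // leaf vote: 0 or 1
};

struct Tree {
  std::vector<Node> nodes;
};

class Rng {
 public:
  explicit Rng(uint64_t seed) : s_(seed * 6364136223846793005ULL + 1442695040888963407ULL) {
    next(); next();
  }
  uint64_t next() {
    // splitmix64
    uint64_t z = (s_ += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int below(int n) {
    return static_cast<int>((static_cast<__uint128_t>(next()) * n) >> 64);
  }
 private:
  uint64_t s_;
};

// Grow one tree on the bootstrap sample `idx`; recursion via explicit stack.
void grow_tree(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int mtry, Rng& rng, Tree& tree) {
  const int p = X.ncol();
  struct Job { int lo, hi, node; };
  std::vector<Job> stack;
  tree.nodes.push_back({-1, 0.0, -1, -1, 0});
  stack.push_back({0, static_cast<int>(idx.size()), 0});

  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;

  while (!stack.empty()) {
    Job job = stack.back();
    stack.pop_back();
    const int n = job.hi - job.lo;
    int n1 = 0;
    for (int i = job.lo; i < job.hi; ++i) n1 += y[idx[i]];

    auto make_leaf = [&]() {
      tree.nodes[job.node].feat = -1;
      tree.nodes[job.node].pred = (2 * n1 > n) ? 1 : 0;
    };

    if (n < 2 || n1 == 0 || n1 == n) { make_leaf(); continue; }

    // sample mtry candidate features without replacement (partial Fisher-Yates)
    const int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + rng.below(p - j);
      std::swap(feats[j], feats[k]);
    }

    const double parent_imp = 1.0 - (double)n1 / n * (double)n1 / n
                                  - (double)(n - n1) / n * (double)(n - n1) / n;
    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-12;

    std::vector<std::pair<double, int>> vals(n);
    for (int fi = 0; fi < m; ++fi) {
      const int f = feats[fi];
      for (int i = 0; i < n; ++i) {
        const int r = idx[job.lo + i];
        vals[i] = {X(r, f), y[r]};
      }
      std::sort(vals.begin(), vals.end());
      int l1 = 0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1, nr = n - nl;
        const int r1 = n1 - l1;
        const double gl = 1.0 - (double)l1 / nl * (double)l1 / nl
                              - (double)(nl - l1) / nl * (double)(nl - l1) / nl;
        const double gr = 1.0 - (double)r1 / nr * (double)r1 / nr
                              - (double)(nr - r1) / nr * (double)(nr - r1) / nr;
        const double gain = parent_imp - ((double)nl / n) * gl - ((double)nr / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_f < 0) { make_leaf(); continue; }

    // partition idx[lo, hi) in place
    int mid = job.lo;
    for (int i = job.lo; i < job.hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
    }
    if (mid == job.lo || mid == job.hi) { make_leaf(); continue; }

    const int li = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back({-1, 0.0, -1, -1, 0});
    tree.nodes.push_back({-1, 0.0, -1, -1, 0});
    tree.nodes[job.node].feat = best_f;
    tree.nodes[job.node].thr = best_thr;
    tree.nodes[job.node].left = li;
    tree.nodes[job.node].right = li + 1;
    stack.push_back({job.lo, mid, li});
    stack.push_back({mid, job.hi, li + 1});
  }
}

int predict_tree(const Tree& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree.nodes[node].feat >= 0) {
    node = (X(row, tree.nodes[node].feat) <= tree.nodes[node].thr)
               ? tree.nodes[node].left
               : tree.nodes[node].right;
  }
  return tree.nodes[node].pred;
}

}  // namespace

// Fit a forest on (X, y) and return the fraction of trees voting class 1
// for each row of Xtest. y must be 0/1.
// [[Rcpp::export(name = ".rf_fit_predict")]]
NumericVector rf_fit_predict(NumericMatrix X, IntegerVector y,
                             NumericMatrix Xtest, int ntree, int mtry,
                             double seed) {
  const int n = X.nrow();
  if (n != y.size()) stop("X and y sizes differ");
  if (ntree < 1) stop("ntree must be >= 1");
  if (mtry < 1) mtry = 1;
  Rng rng(static_cast<uint64_t>(seed) + 0x517cc1b727220a95ULL);

  const int ntest = Xtest.nrow();
  std::vector<int> votes(ntest, 0);
  std::vector<int> idx(n);
  Tree tree;
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);  // bootstrap sample
    tree.nodes.clear();
    grow_tree(X, y, idx, mtry, rng, tree);
    for (int i = 0; i < ntest; ++i) votes[i] += predict_tree(tree, Xtest, i);
  }
  NumericVector out(ntest);
  for (int i = 0; i < ntest; ++i) out[i] = (double)votes[i] / ntree;
  return out;
}
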