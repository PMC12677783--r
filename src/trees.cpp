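#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// CART-style regression trees (squared-error splits), used as the base
// learner for both the bagged random forest (0/1 response, averaged to a
// class probability; equivalent to Gini for binary targets) and logistic
// gradient boosting (trees fit to pseudo-residuals).

struct TRng {
  uint64_t s;
  explicit TRng(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() { s ^= s >> 12; s ^= s << 25; s ^= s >> 27; return s * 0x2545F4914F6CDD1DULL; }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feat, left, right;
  std::vector<double> thr, value;
};

struct BuildCtx {
  const double *X; // n x p column-major
  const double *y;
  const double *grad_w; // optional weights for leaf values (Newton step); NULL -> mean
  int n, p, mtry, max_depth, min_node;
  TRng *rng;
  Tree *tree;
};

static int build_node(BuildCtx &c, std::vector<int> &idx, int lo, int hi, int depth) {
  int node = (int)c.tree->feat.size();
  c.tree->feat.push_back(-1);
  c.tree->thr.push_back(0.0);
  c.tree->left.push_back(-1);
  c.tree->right.push_back(-1);
  c.tree->value.push_back(0.0);

  int nn = hi - lo;
  double sum = 0.0, wsum = 0.0;
  for (int k = lo; k < hi; ++k) sum += c.y[idx[k]];
  if (c.grad_w) {
    for (int k = lo; k < hi; ++k) wsum += c.grad_w[idx[k]];
    c.tree->value[node] = sum / std::max(wsum, 1e-10);
  } else {
    c.tree->value[node] = sum / nn;
  }
  if (depth >= c.max_depth || nn < 2 * c.min_node) return node;

  // is the response constant?
  bool constant = true;
  for (int k = lo + 1; k < hi; ++k)
    if (c.y[idx[k]] != c.y[idx[lo]]) { constant = false; break; }
  if (constant) return node;

  // candidate features
  std::vector<int> feats(c.p);
  for (int j = 0; j < c.p; ++j) feats[j] = j;
  for (int j = 0; j < c.mtry && j < c.p; ++j) {
    int r = j + c.rng->below(c.p - j);
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double,double>> vals(nn); // (x, y)
  double tot = sum;
  for (int fj = 0; fj < std::min(c.mtry, c.p); ++fj) {
    int f = feats[fj];
    const double *col = c.X + (size_t)f * c.n;
    for (int k = 0; k < nn; ++k) {
      int i = idx[lo + k];
      vals[k] = std::make_pair(col[i], c.y[i]);
    }
    std::sort(vals.begin(), vals.end());
    double lsum = 0.0;
    for (int k = 0; k < nn - 1; ++k) {
      lsum += vals[k].second;
      if (vals[k].first == vals[k + 1].first) continue;
      int nl = k + 1, nr = nn - nl;
      if (nl < c.min_node || nr < c.min_node) continue;
      double rsum = tot - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - tot * tot / nn;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_f < 0) return node;

  // partition idx[lo..hi) in place
  const double *col = c.X + (size_t)best_f * c.n;
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (col[idx[k]] <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return node;

  c.tree->feat[node] = best_f;
  c.tree->thr[node] = best_thr;
  int l = build_node(c, idx, lo, mid, depth + 1);
  c.tree->left[node] = l;
  int r = build_node(c, idx, mid, hi, depth + 1);
  c.tree->right[node] = r;
  return node;
}

static Tree fit_tree(const double *X, const double *y, const double *gw,
                     std::vector<int> idx, int n, int p, int mtry,
                     int max_depth, int min_node, TRng &rng) {
  Tree t;
  BuildCtx c{X, y, gw, n, p, mtry, max_depth, min_node, &rng, &t};
  build_node(c, idx, 0, (int)idx.size(), 0);
  return t;
}

static double predict_one(const Tree &t, const double *X, int n, int i) {
  int node = 0;
  while (t.feat[node] >= 0) {
    double v = X[(size_t)t.feat[node] * n + i];
    node = (v <= t.thr[node]) ? t.left[node] : t.right[node];
  }
  return t.value[node];
}

static List tree_to_list(const Tree &t) {
  return List::create(_["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
                      _["left"] = wrap(t.left), _["right"] = wrap(t.right),
                      _["value"] = wrap(t.value));
}

static Tree tree_from_list(List l) {
  Tree t;
  t.feat = as<std::vector<int>>(l["feat"]);
  t.thr = as<std::vector<double>>(l["thr"]);
  t.left = as<std::vector<int>>(l["left"]);
  t.right = as<std::vector<int>>(l["right"]);
  t.value = as<std::vector<double>>(l["value"]);
  return t;
}

// Random forest on a 0/1 response: bootstrap + feature subsampling,
// prediction = mean leaf value (class probability).
// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix Xm, NumericVector ym, int ntree, int mtry,
                int max_depth, int min_node, double seed) {
  int n = Xm.nrow(), p = Xm.ncol();
  TRng rng((uint64_t)seed + 0xF0AE57ULL);
  List trees(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.below(n);
    Tree t = fit_tree(&Xm[0], &ym[0], nullptr, idx, n, p, mtry, max_depth,
                      min_node, rng);
    trees[b] = tree_to_list(t);
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector forest_predict_cpp(List trees, NumericMatrix Xm) {
  int n = Xm.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += predict_one(t, &Xm[0], n, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// Binomial gradient boosting (Friedman): trees fit to y - p with one-step
// Newton leaf values sum(r)/sum(p(1-p)); returns trees + intercept.
// [[Rcpp::export]]
List gb_fit_cpp(NumericMatrix Xm, NumericVector ym, int ntree, int max_depth,
                int min_node, double shrinkage, double seed) {
  int n = Xm.nrow(), p = Xm.ncol();
  TRng rng((uint64_t)seed + 0x6B0057ULL);
  double ybar = mean(ym);
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double F0 = std::log(ybar / (1.0 - ybar));
  std::vector<double> F(n, F0), resid(n), hess(n);
  List trees(ntree);
  std::vector<int> idx0(n);
  for (int i = 0; i < n; ++i) idx0[i] = i;
  for (int b = 0; b < ntree; ++b) {
    for (int i = 0; i < n; ++i) {
      double pi = 1.0 / (1.0 + std::exp(-F[i]));
      resid[i] = ym[i] - pi;
      hess[i] = std::max(pi * (1.0 - pi), 1e-6);
    }
    Tree t = fit_tree(&Xm[0], resid.data(), hess.data(), idx0, n, p, p,
                      max_depth, min_node, rng);
    for (int i = 0; i < n; ++i)
      F[i] += shrinkage * predict_one(t, &Xm[0], n, i);
    trees[b] = tree_to_list(t);
  }
  return List::create(_["trees"] = trees, _["F0"] = F0,
                      _["shrinkage"] = shrinkage);
}

// [[Rcpp::export]]
NumericVector gb_predict_cpp(List model, NumericMatrix Xm) {
  List trees = model["trees"];
  double F0 = model["F0"], shr = model["shrinkage"];
  int n = Xm.nrow(), B = trees.size();
  NumericVector out(n, F0);
  for (int b = 0; b < B; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) out[i] += shr * predict_one(t, &Xm[0], n, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-out[i]));
  return out;
}
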