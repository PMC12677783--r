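#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Small deterministic RNG (xorshift64*) so that partitions are reproducible
// under a user seed independently of R's RNG state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static void shuffle_order(std::vector<int> &ord, XorShift &rng) {
  for (int i = (int)ord.size() - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(ord[i], ord[j]);
  }
}

// One Louvain level: greedy local moves on gain matrix B (dense, symmetric).
// Maximizes sum_{i!=j} B[i,j] * [c_i == c_j]. Returns community labels
// (0-based, contiguous). Ties between candidate communities are broken in
// favour of the lowest community id; node sweep order is shuffled per seed.
static std::vector<int> local_moves(const std::vector<double> &B, int n,
                                    XorShift &rng,
                                    const std::vector<int> *init = nullptr) {
  std::vector<int> comm(n);
  if (init) comm = *init;
  else for (int i = 0; i < n; ++i) comm[i] = i;
  std::vector<double> gain(n, 0.0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;

  bool improved = true;
  int guard = 0;
  while (improved && guard++ < 1000) {
    improved = false;
    shuffle_order(ord, rng);
    for (int oi = 0; oi < n; ++oi) {
      int i = ord[oi];
      // link strength from i to each community (excluding self-loop B_ii)
      std::fill(gain.begin(), gain.end(), 0.0);
      const double *Bi = &B[(size_t)i * n];
      for (int j = 0; j < n; ++j)
        if (j != i) gain[comm[j]] += Bi[j];
      int own = comm[i];
      double stay = gain[own];
      int best = own;
      double best_gain = stay;
      for (int c = 0; c < n; ++c) {
        if (c == own) continue;
        if (gain[c] > best_gain + 1e-12) { best_gain = gain[c]; best = c; }
      }
      if (best != own) { comm[i] = best; improved = true; }
    }
  }
  // relabel contiguous by first occurrence
  std::vector<int> map(n, -1);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = k++;
    comm[i] = map[comm[i]];
  }
  return comm;
}

static double gain_of(const std::vector<double> &B, int n,
                      const std::vector<int> &lab) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *Bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      if (lab[i] == lab[j]) s += Bi[j];
  }
  return s;
}

// One multi-level Louvain pass (local moves + aggregation), first level
// optionally warm-started from `init`.
static std::vector<int> louvain_pass(const std::vector<double> &B, int n,
                                     XorShift &rng,
                                     const std::vector<int> *init) {
  std::vector<int> labels = local_moves(B, n, rng, init);
  int ncur = 1 + *std::max_element(labels.begin(), labels.end());
  if (ncur == n) return labels;
  // aggregate and recurse on super-nodes
  std::vector<double> Bcur((size_t)ncur * ncur, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *Bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      Bcur[(size_t)labels[i] * ncur + labels[j]] += Bi[j];
  }
  for (int level = 0; level < 100; ++level) {
    std::vector<int> part = local_moves(Bcur, ncur, rng, nullptr);
    int k = 1 + *std::max_element(part.begin(), part.end());
    if (k == ncur) break;
    for (int i = 0; i < n; ++i) labels[i] = part[labels[i]];
    std::vector<double> Bnew((size_t)k * k, 0.0);
    for (int i = 0; i < ncur; ++i)
      for (int j = 0; j < ncur; ++j)
        Bnew[(size_t)part[i] * k + part[j]] += Bcur[(size_t)i * ncur + j];
    Bcur.swap(Bnew);
    ncur = k;
    if (k == 1) break;
  }
  return labels;
}

// Iterated Louvain: repeat full passes, warm-starting each from the
// previous partition, until the objective stops improving. The node-level
// restart lets single nodes escape communities frozen by aggregation.
static std::vector<int> louvain_iterate(const std::vector<double> &B, int n,
                                        XorShift &rng,
                                        const std::vector<int> *init) {
  std::vector<int> labels = louvain_pass(B, n, rng, init);
  double g = gain_of(B, n, labels);
  for (int it = 0; it < 50; ++it) {
    std::vector<int> nxt = louvain_pass(B, n, rng, &labels);
    double g2 = gain_of(B, n, nxt);
    if (g2 <= g + 1e-10) break;
    labels = nxt;
    g = g2;
  }
  return labels;
}

// Full Louvain: iterated local moves + aggregation until stable.
// B is a dense symmetric gain matrix (e.g. modularity matrix W - g*k k^T/2m,
// or a multilayer supra-modularity matrix with inter-layer coupling).
// [[Rcpp::export]]
IntegerVector louvain_gain_cpp(NumericMatrix Bmat, double seed,
                               Rcpp::Nullable<IntegerVector> init = R_NilValue) {
  int n = Bmat.nrow();
  if (n != Bmat.ncol()) stop("gain matrix must be square");
  std::vector<double> B(Bmat.begin(), Bmat.end());
  XorShift rng((uint64_t)seed + 0x51ED2700ULL);
  std::vector<int> labels;
  if (init.isNotNull()) {
    IntegerVector iv(init);
    if (iv.size() != n) stop("init labels must have one entry per node");
    std::vector<int> in0(n), map(n + 1, -1);
    int k = 0;
    for (int i = 0; i < n; ++i) {
      int v = iv[i] - 1;
      if (v < 0 || v >= n) stop("init labels out of range");
      if (map[v] < 0) map[v] = k++;
      in0[i] = map[v];
    }
    labels = louvain_iterate(B, n, rng, &in0);
  } else {
    labels = louvain_iterate(B, n, rng, nullptr);
  }
  // contiguous from 1 by first occurrence over original node order
  std::vector<int> map(n, -1);
  int k = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (map[labels[i]] < 0) map[labels[i]] = ++k;
    out[i] = map[labels[i]];
  }
  return out;
}

static double partition_gain(const std::vector<double> &B, int n,
                             const IntegerVector &lab) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *Bi = &B[(size_t)i * n];
    for (int j = 0; j < n; ++j)
      if (lab[i] == lab[j]) s += Bi[j];
  }
  return s;
}

// Run Louvain from n_init different seeded initial sweep orders and return
// the labels with the highest total gain sum_{ij} B_ij [c_i == c_j]
// (diagonal included; it is partition-independent).
// [[Rcpp::export]]
List louvain_best_cpp(NumericMatrix Bmat, int n_init, double seed,
                      Rcpp::Nullable<IntegerVector> init = R_NilValue) {
  int n = Bmat.nrow();
  std::vector<double> B(Bmat.begin(), Bmat.end());
  IntegerVector best;
  double best_gain = -1e300;
  for (int r = 0; r < n_init; ++r) {
    // the first run can be warm-started (e.g. from per-layer partitions)
    IntegerVector lab = (r == 0 && init.isNotNull())
      ? louvain_gain_cpp(Bmat, seed + r, init)
      : louvain_gain_cpp(Bmat, seed + r);
    double g = partition_gain(B, n, lab);
    if (g > best_gain + 1e-12) { best_gain = g; best = lab; }
  }
  return List::create(_["labels"] = best, _["gain"] = best_gain);
}

// Degree-preserving rewiring of the binary skeleton (Maslov-Sneppen double
// edge swaps) followed by a shuffle of the original weight multiset over the
// rewired edge slots. Returns the surrogate adjacency matrix.
// [[Rcpp::export]]
NumericMatrix rewire_shuffle_cpp(NumericMatrix W, int n_swaps, double seed) {
  int n = W.nrow();
  XorShift rng((uint64_t)seed + 0xABCD01ULL);
  // collect edges i<j
  std::vector<int> ei, ej;
  std::vector<double> wts;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (W(i, j) != 0.0) { ei.push_back(i); ej.push_back(j); wts.push_back(W(i, j)); }
  int m = (int)ei.size();
  if (m < 2) stop("too few edges to rewire");
  if (m == n * (n - 1) / 2) n_swaps = 0; // complete graph: rewiring is a no-op
  // adjacency lookup
  std::vector<char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e) adj[(size_t)ei[e] * n + ej[e]] = adj[(size_t)ej[e] * n + ei[e]] = 1;
  int done = 0, tries = 0, max_tries = 100 * n_swaps + 100;
  while (done < n_swaps && tries++ < max_tries) {
    int e1 = rng.below(m), e2 = rng.below(m);
    if (e1 == e2) continue;
    int a = ei[e1], b = ej[e1], c = ei[e2], d = ej[e2];
    if (rng.below(2)) std::swap(c, d); // choose orientation
    // proposed new edges (a,d) and (c,b)
    if (a == d || c == b || a == c || b == d) continue;
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 0;
    adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 0;
    adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 1;
    adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 1;
    ej[e1] = d; ei[e2] = c; ej[e2] = b;
    if (ei[e1] > ej[e1]) std::swap(ei[e1], ej[e1]);
    if (ei[e2] > ej[e2]) std::swap(ei[e2], ej[e2]);
    ++done;
  }
  // shuffle the weight multiset over edge slots
  for (int i = m - 1; i > 0; --i) {
    int j = rng.below(i + 1);
    std::swap(wts[i], wts[j]);
  }
  NumericMatrix S(n, n);
  for (int e = 0; e < m; ++e) {
    S(ei[e], ej[e]) = wts[e];
    S(ej[e], ei[e]) = wts[e];
  }
  return S;
}
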