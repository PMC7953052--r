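#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Shared xorshift128+ generator: deterministic across platforms,
// independent of R's RNG stream.
struct XRng {
  uint64_t s0, s1;
  explicit XRng(uint64_t seed) {
    // splitmix64 to spread the seed
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto mix = [](uint64_t &z) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      return x ^ (x >> 31);
    };
    s0 = mix(z); s1 = mix(z);
    if (s0 == 0 && s1 == 0) s1 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return (int)(unif() * n); }
};

// Gauss-Seidel sweeps on (D + sigma I - A) x = 0: in-place coordinate
// updates x_i <- sum_j A_ij x_j / (d_i + sigma), one column at a time.
// [[Rcpp::export]]
NumericMatrix gauss_seidel_smooth(IntegerVector ptr, IntegerVector idx,
                                  NumericVector w, NumericMatrix x0,
                                  int iters, double sigma) {
  int n = x0.nrow(), t = x0.ncol();
  NumericMatrix x = clone(x0);
  std::vector<double> deg(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) deg[i] += w[e];
  for (int c = 0; c < t; ++c) {
    for (int it = 0; it < iters; ++it) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int e = ptr[i]; e < ptr[i + 1]; ++e) acc += w[e] * x(idx[e], c);
        x(i, c) = acc / (deg[i] + sigma);
      }
    }
  }
  return x;
}

static inline int weighted_pick(const std::vector<double> &cum, XRng &rng) {
  double r = rng.unif() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
}

static inline bool has_neighbor(const IntegerVector &ptr,
                                const IntegerVector &idx, int u, int x) {
  const int *b = &idx[0] + ptr[u], *e = &idx[0] + ptr[u + 1];
  return std::binary_search(b, e, x); // neighbor lists sorted by id
}

// Random-walk corpus. mode 0 = first-order weighted walk (DeepWalk),
// mode 1 = second-order biased walk (node2vec) with factors 1/p (return),
// 1 (distance-1), 1/q (distance-2). num_walks epochs; within each epoch
// every node starts one walk, in shuffled order. Isolated nodes emit the
// singleton walk [v].
// [[Rcpp::export]]
List walk_corpus(IntegerVector ptr, IntegerVector idx, NumericVector w,
                 int n, int num_walks, int walk_len, int mode,
                 double p, double q, int seed) {
  XRng rng((uint64_t)seed);
  List corpus(n * num_walks);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<int> walk;
  std::vector<double> cum;
  int out = 0;
  for (int r = 0; r < num_walks; ++r) {
    // Fisher-Yates shuffle of start nodes
    for (int i = n - 1; i > 0; --i)
      std::swap(order[i], order[rng.below(i + 1)]);
    for (int s = 0; s < n; ++s) {
      int cur = order[s];
      walk.clear();
      walk.push_back(cur);
      int prev = -1;
      while ((int)walk.size() < walk_len) {
        int lo = ptr[cur], hi = ptr[cur + 1];
        if (hi == lo) break; // dead end (isolated node)
        cum.assign(hi - lo, 0.0);
        double acc = 0.0;
        for (int e = lo; e < hi; ++e) {
          double wt = w[e];
          if (mode == 1 && prev >= 0) {
            int x = idx[e];
            if (x == prev) wt /= p;
            else if (!has_neighbor(ptr, idx, prev, x)) wt /= q;
            // distance-1 (x adjacent to prev): factor 1
          }
          acc += wt;
          cum[e - lo] = acc;
        }
        int pick = lo + weighted_pick(cum, rng);
        prev = cur;
        cur = idx[pick];
        walk.push_back(cur);
      }
      corpus[out++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return corpus;
}

// Skip-gram with negative sampling over a walk corpus of 0-based node
// ids. Standard word2vec scheme: per position a reduced window
// b ~ U{0..window-1} keeps contexts within window-b; unigram^0.75
// negative-sampling table; input vectors ~ U(-0.5/d, 0.5/d), output
// vectors start at zero; linear learning-rate decay. Returns the input
// (N x d) matrix; nodes absent from the corpus keep zero rows.
// [[Rcpp::export]]
NumericMatrix sgns_train(List corpus, int n_nodes, int dim, int window,
                         int epochs, int negative, double alpha0,
                         int seed) {
  XRng rng((uint64_t)seed);
  std::vector<std::vector<int>> walks;
  walks.reserve(corpus.size());
  std::vector<double> freq(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < corpus.size(); ++i) {
    IntegerVector wv = corpus[i];
    walks.emplace_back(wv.begin(), wv.end());
    for (int t : walks.back()) { freq[t] += 1.0; ++total_tokens; }
  }
  if (total_tokens == 0) stop("empty walk corpus");

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> negcum(n_nodes, 0.0);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) {
    acc += (freq[i] > 0) ? std::pow(freq[i], 0.75) : 0.0;
    negcum[i] = acc;
  }

  std::vector<double> U((size_t)n_nodes * dim, 0.0);
  std::vector<double> V((size_t)n_nodes * dim, 0.0);
  for (int i = 0; i < n_nodes; ++i) {
    // nodes absent from the corpus keep zero rows
    if (freq[i] > 0)
      for (int d = 0; d < dim; ++d)
        U[(size_t)i * dim + d] = (rng.unif() - 0.5) / dim;
    else
      for (int d = 0; d < dim; ++d) rng.unif(); // keep the stream aligned
  }

  const double alpha_min = alpha0 * 1e-4;
  long long processed = 0;
  const long long grand = (long long)epochs * total_tokens;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < walks.size(); ++wi) {
      const std::vector<int> &walk = walks[wi];
      int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)grand);
        if (alpha < alpha_min) alpha = alpha_min;
        ++processed;
        int center = walk[pos];
        int b = rng.below(window);
        int lo = std::max(0, pos - window + b);
        int hi = std::min(len - 1, pos + window - b);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          int ctx = walk[j];
          double *u = &U[(size_t)ctx * dim]; // word2vec: context as input
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = center; label = 1.0; }
            else {
              double r = rng.unif() * acc;
              target = (int)(std::lower_bound(negcum.begin(), negcum.end(),
                                              r) - negcum.begin());
              if (target == center) continue;
              label = 0.0;
            }
            double *v = &V[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += u[d] * v[d];
            double g = (label - 1.0 / (1.0 + std::exp(-dot))) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v[d];
              v[d] += g * u[d];
            }
          }
          for (int d = 0; d < dim; ++d) u[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = U[(size_t)i * dim + d];
  return out;
}
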