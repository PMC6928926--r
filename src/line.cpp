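// LINE-style network embedding: alias sampling, negative sampling SGD.
// Self-contained RNG (xorshift64*) so results are bit-reproducible across
// platforms for a given seed.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scramble of the seed so small seeds give distinct streams
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = (z ^ (z >> 31)) | 1ULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n); }
};

struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;

  void build(const std::vector<double>& w) {
    int n = (int)w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> scaled(n);
    for (int i = 0; i < n; ++i) scaled[i] = w[i] * n / total;
    std::vector<int> small, large;
    small.reserve(n);
    large.reserve(n);
    for (int i = n - 1; i >= 0; --i) {
      if (scaled[i] < 1.0) small.push_back(i);
      else large.push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      if (scaled[l] < 1.0) small.push_back(l);
      else large.push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  int draw(XRng& rng) const {
    int k = rng.below((int)prob.size());
    return rng.unif() < prob[k] ? k : alias[k];
  }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
List alias_build_cpp(NumericVector weights) {
  int n = weights.size();
  if (n == 0) stop("cannot build an alias table from zero weights");
  std::vector<double> w(weights.begin(), weights.end());
  for (double x : w) {
    if (!(x > 0) || !R_finite(x)) stop("alias weights must be finite and > 0");
  }
  AliasTable t;
  t.build(w);
  return List::create(_["prob"] = NumericVector(t.prob.begin(), t.prob.end()),
                      _["alias"] = IntegerVector(t.alias.begin(), t.alias.end()));
}

// [[Rcpp::export]]
IntegerVector alias_sample_cpp(NumericVector prob, IntegerVector alias, int n,
                               int seed) {
  AliasTable t;
  t.prob.assign(prob.begin(), prob.end());
  t.alias.assign(alias.begin(), alias.end());
  XRng rng((uint64_t)seed);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = t.draw(rng) + 1;  // 1-based
  return out;
}

// Train one LINE half (order 1 or 2) by SGD with negative sampling.
//
// src/dst: 0-based directed edge endpoints (each undirected edge passed in
// both directions); weight: positive edge weights. Negative nodes are drawn
// from a noise distribution proportional to (weighted degree)^0.75.
// Learning rate decays linearly from rho0 to rho0 * 1e-4.
//
// Returns list(embedding = n_nodes x dim matrix,
//              loss = mean negative-sampling loss per window).
// [[Rcpp::export]]
List line_train_cpp(IntegerVector src, IntegerVector dst, NumericVector weight,
                    int n_nodes, int dim, int order, int n_negative,
                    double total_samples, double rho0, int seed,
                    int n_loss_windows = 20) {
  int n_edges = src.size();
  if (n_edges == 0) stop("cannot embed an edgeless graph");
  if (dim < 1) stop("dim must be >= 1");
  if (order != 1 && order != 2) stop("order must be 1 or 2");
  if (n_negative < 1) stop("n_negative must be >= 1");

  XRng rng((uint64_t)seed);

  // edge sampling proportional to weight
  std::vector<double> w(weight.begin(), weight.end());
  AliasTable edge_tab;
  edge_tab.build(w);

  // noise distribution over nodes: degree^0.75 (weighted)
  std::vector<double> deg(n_nodes, 0.0);
  for (int e = 0; e < n_edges; ++e) deg[src[e]] += w[e];
  std::vector<double> noise(n_nodes);
  bool any_pos = false;
  for (int i = 0; i < n_nodes; ++i) {
    noise[i] = deg[i] > 0 ? std::pow(deg[i], 0.75) : 0.0;
    any_pos = any_pos || noise[i] > 0;
  }
  if (!any_pos) stop("no node has positive degree");
  // alias needs strictly positive weights: drop zero-degree nodes from noise
  std::vector<int> noise_ids;
  std::vector<double> noise_w;
  for (int i = 0; i < n_nodes; ++i) {
    if (noise[i] > 0) { noise_ids.push_back(i); noise_w.push_back(noise[i]); }
  }
  AliasTable node_tab;
  node_tab.build(noise_w);

  // vertex vectors: uniform(-0.5/dim, 0.5/dim); context vectors: zero
  std::vector<double> emb((size_t)n_nodes * dim);
  for (auto& x : emb) x = (rng.unif() - 0.5) / dim;
  std::vector<double> ctx;
  if (order == 2) ctx.assign((size_t)n_nodes * dim, 0.0);
  std::vector<double>& target = (order == 2) ? ctx : emb;

  long long T = (long long)total_samples;
  int n_win = n_loss_windows > 0 ? n_loss_windows : 1;
  long long win_size = T > 0 ? std::max(1LL, T / n_win) : 1;
  std::vector<double> win_loss;
  double acc_loss = 0.0;
  long long acc_n = 0;

  std::vector<double> grad_u(dim);

  for (long long s = 0; s < T; ++s) {
    double frac = (double)s / (double)T;
    double lr = rho0 * std::max(1.0 - frac, 1e-4);

    int e = edge_tab.draw(rng);
    int u = src[e], v = dst[e];
    double* eu = &emb[(size_t)u * dim];
    std::fill(grad_u.begin(), grad_u.end(), 0.0);
    double loss = 0.0;

    for (int d = 0; d <= n_negative; ++d) {
      int tgt;
      double label;
      if (d == 0) {
        tgt = v;
        label = 1.0;
      } else {
        tgt = noise_ids[node_tab.draw(rng)];
        if (tgt == v) continue;
        label = 0.0;
      }
      double* et = &target[(size_t)tgt * dim];
      double x = 0.0;
      for (int k = 0; k < dim; ++k) x += eu[k] * et[k];
      double p = sigmoid(x);
      double g = (label - p) * lr;
      loss -= label > 0.5 ? std::log(std::max(p, 1e-12))
                          : std::log(std::max(1.0 - p, 1e-12));
      for (int k = 0; k < dim; ++k) {
        grad_u[k] += g * et[k];
        et[k] += g * eu[k];
      }
    }
    for (int k = 0; k < dim; ++k) eu[k] += grad_u[k];

    acc_loss += loss;
    acc_n += 1;
    if (acc_n == win_size) {
      win_loss.push_back(acc_loss / acc_n);
      acc_loss = 0.0;
      acc_n = 0;
    }
  }
  if (acc_n > 0) win_loss.push_back(acc_loss / acc_n);

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = emb[(size_t)i * dim + k];
  return List::create(_["embedding"] = out,
                      _["loss"] = NumericVector(win_loss.begin(), win_loss.end()));
}
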