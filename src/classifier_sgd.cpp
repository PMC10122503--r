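#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// FNV-1a 32-bit hash of each n-gram string, mapped to 1-based bucket ids.
// [[Rcpp::export]]
IntegerVector hash_ngrams_cpp(CharacterVector ngrams, int buckets) {
  R_xlen_t n = ngrams.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(ngrams, i));
    uint32_t h = 2166136261u;
    for (const char *p = s; *p; ++p) {
      h ^= (uint8_t)(*p);
      h *= 16777619u;
    }
    out[i] = (int)(h % (uint32_t)buckets) + 1;
  }
  return out;
}

// Stochastic gradient descent on softmax cross-entropy for an averaged
// hashed-n-gram embedding model: score = W %*% mean(E[buckets, ]).
// `order` is an n x epochs matrix of 1-based visit orders supplied by the
// caller so that all randomness stays in R's RNG. Learning rate decays
// linearly to zero over the full pass. Single-threaded and deterministic.
// [[Rcpp::export]]
List sgd_train_cpp(List docs, IntegerVector labels, NumericMatrix E0,
                   NumericMatrix W0, int epochs, double lr0,
                   IntegerMatrix order) {
  NumericMatrix E = clone(E0);  // buckets x dim
  NumericMatrix W = clone(W0);  // K x dim
  int dim = E.ncol();
  int K = W.nrow();
  R_xlen_t n = docs.size();
  double total = (double)epochs * (double)n;
  double t = 0.0;
  NumericVector epoch_loss(epochs);
  std::vector<double> h(dim), dh(dim), g(K), sc(K);

  for (int e = 0; e < epochs; ++e) {
    double loss = 0.0;
    long counted = 0;
    for (R_xlen_t ii = 0; ii < n; ++ii) {
      int i = order(ii, e) - 1;
      IntegerVector b = docs[i];
      int nb = b.size();
      if (nb == 0) { t += 1.0; continue; }
      double lr = lr0 * (1.0 - t / total);
      for (int d = 0; d < dim; ++d) h[d] = 0.0;
      for (int j = 0; j < nb; ++j) {
        int r = b[j] - 1;
        for (int d = 0; d < dim; ++d) h[d] += E(r, d);
      }
      for (int d = 0; d < dim; ++d) h[d] /= nb;

      double mx = -1e300;
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int d = 0; d < dim; ++d) s += W(k, d) * h[d];
        sc[k] = s;
        if (s > mx) mx = s;
      }
      double Z = 0.0;
      for (int k = 0; k < K; ++k) { sc[k] = std::exp(sc[k] - mx); Z += sc[k]; }
      int y = labels[i] - 1;
      loss += -std::log(sc[y] / Z + 1e-15);
      ++counted;
      for (int k = 0; k < K; ++k) g[k] = sc[k] / Z - (k == y ? 1.0 : 0.0);

      for (int d = 0; d < dim; ++d) dh[d] = 0.0;
      for (int k = 0; k < K; ++k) {
        double gk = g[k];
        for (int d = 0; d < dim; ++d) {
          dh[d] += W(k, d) * gk;
          W(k, d) -= lr * gk * h[d];
        }
      }
      double scale = lr / nb;
      for (int j = 0; j < nb; ++j) {
        int r = b[j] - 1;
        for (int d = 0; d < dim; ++d) E(r, d) -= scale * dh[d];
      }
      t += 1.0;
    }
    epoch_loss[e] = counted > 0 ? loss / counted : NA_REAL;
  }
  return List::create(_["embeddings"] = E, _["class_weights"] = W,
                      _["epoch_loss"] = epoch_loss);
}

// Forward pass: n x K softmax probabilities; documents with no features get
// a uniform distribution (flagged separately on the R side).
// [[Rcpp::export]]
NumericMatrix softmax_predict_cpp(List docs, NumericMatrix E, NumericMatrix W) {
  int dim = E.ncol();
  int K = W.nrow();
  R_xlen_t n = docs.size();
  NumericMatrix out(n, K);
  std::vector<double> h(dim), sc(K);
  for (R_xlen_t i = 0; i < n; ++i) {
    IntegerVector b = docs[i];
    int nb = b.size();
    if (nb == 0) {
      for (int k = 0; k < K; ++k) out(i, k) = 1.0 / K;
      continue;
    }
    for (int d = 0; d < dim; ++d) h[d] = 0.0;
    for (int j = 0; j < nb; ++j) {
      int r = b[j] - 1;
      for (int d = 0; d < dim; ++d) h[d] += E(r, d);
    }
    for (int d = 0; d < dim; ++d) h[d] /= nb;
    double mx = -1e300;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int d = 0; d < dim; ++d) s += W(k, d) * h[d];
      sc[k] = s;
      if (s > mx) mx = s;
    }
    double Z = 0.0;
    for (int k = 0; k < K; ++k) { sc[k] = std::exp(sc[k] - mx); Z += sc[k]; }
    for (int k = 0; k < K; ++k) out(i, k) = sc[k] / Z;
  }
  return out;
}
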