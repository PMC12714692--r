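#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// doc / word are 0-based parallel token vectors (one entry per token
// instance). Draws use R's RNG (unif_rand), so a set.seed() call on the R
// side makes the whole fit bit-reproducible. Returns the final topic-count
// matrices from which smoothed beta/gamma estimates are formed in R.

// [[Rcpp::export(name = ".gibbs_lda_cpp")]]
List gibbs_lda_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int k,
                   double alpha, double eta, int n_iter) {
  const int n_tokens = doc.size();
  IntegerVector z(n_tokens);
  IntegerMatrix ndk(n_docs, k);
  IntegerMatrix nkv(k, n_vocab);
  IntegerVector nk(k);

  // random initialization
  for (int t = 0; t < n_tokens; ++t) {
    int topic = static_cast<int>(unif_rand() * k);
    if (topic == k) topic = k - 1;
    z[t] = topic;
    ndk(doc[t], topic) += 1;
    nkv(topic, word[t]) += 1;
    nk[topic] += 1;
  }

  std::vector<double> p(k);
  const double veta = n_vocab * eta;
  for (int it = 0; it < n_iter; ++it) {
    for (int t = 0; t < n_tokens; ++t) {
      const int d = doc[t];
      const int w = word[t];
      int topic = z[t];
      ndk(d, topic) -= 1;
      nkv(topic, w) -= 1;
      nk[topic] -= 1;

      double total = 0.0;
      for (int j = 0; j < k; ++j) {
        p[j] = (ndk(d, j) + alpha) * (nkv(j, w) + eta) / (nk[j] + veta);
        total += p[j];
      }
      double u = unif_rand() * total;
      double cum = 0.0;
      topic = k - 1;
      for (int j = 0; j < k; ++j) {
        cum += p[j];
        if (u < cum) { topic = j; break; }
      }
      z[t] = topic;
      ndk(d, topic) += 1;
      nkv(topic, w) += 1;
      nk[topic] += 1;
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["ndk"] = ndk, _["nkv"] = nkv, _["nk"] = nk);
}
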