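#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Tokens are the expanded units of the integer gene-by-cell pseudo-count
// matrix: token t belongs to cell doc[t] and gene word[t] (both 0-based).
// theta and phi are integrated out; only per-token topic labels z are
// sampled. The full conditional for token t is
//
//   P(z_t = k | z_-t) \propto (n_dk + alpha) * (n_kw + beta) / (n_k + G*beta)
//
// with n_* excluding token t. All randomness comes from R's RNG (the
// caller is expected to set.seed() beforehand), so runs are reproducible.
//
// Count tables are kept K-contiguous (index d*K + k and w*K + k) so the
// inner loop over topics walks consecutive memory.
//
// estimate = 0: theta/phi from the final sweep's counts.
// estimate = 1: theta/phi averaged over every `thin`-th post-burn-in sweep.
// trace > 0: additionally record the z vector every `trace`-th post-burn-in
// sweep (used to compare the sampler's state distribution against the
// exactly enumerated collapsed posterior on tiny corpora).

// [[Rcpp::export(name = ".gibbs_lda_cpp")]]
List gibbs_lda_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_words, int K,
                   double alpha, double beta,
                   int iterations, int burn_in,
                   int estimate, int thin, int trace) {
  const int T = doc.size();
  const double Gb = n_words * beta;

  IntegerVector z(T);
  std::vector<int> nd_k((size_t)n_docs * K, 0);
  std::vector<int> nw_k((size_t)n_words * K, 0);
  std::vector<int> nk(K, 0);
  std::vector<int> nd(n_docs, 0);

  // random initial assignment
  for (int t = 0; t < T; ++t) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[t] = k;
    nd_k[(size_t)doc[t] * K + k]++;
    nw_k[(size_t)word[t] * K + k]++;
    nk[k]++;
    nd[doc[t]]++;
  }

  std::vector<double> p(K);
  std::vector<double> denom(K);
  std::vector<double> theta_acc, phi_acc;
  if (estimate == 1) {
    theta_acc.assign((size_t)n_docs * K, 0.0);
    phi_acc.assign((size_t)n_words * K, 0.0);
  }
  int n_acc = 0;

  std::vector<IntegerVector> traces;

  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < K; ++j) denom[j] = 1.0 / (nk[j] + Gb);
    for (int t = 0; t < T; ++t) {
      const int d = doc[t], w = word[t];
      int k = z[t];
      int *ndk = &nd_k[(size_t)d * K];
      int *nwk = &nw_k[(size_t)w * K];
      ndk[k]--; nwk[k]--; nk[k]--;
      denom[k] = 1.0 / (nk[k] + Gb);

      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        tot += (ndk[j] + alpha) * (nwk[j] + beta) * denom[j];
        p[j] = tot;
      }
      const double u = unif_rand() * tot;
      k = 0;
      while (k < K - 1 && p[k] < u) ++k;

      z[t] = k;
      ndk[k]++; nwk[k]++; nk[k]++;
      denom[k] = 1.0 / (nk[k] + Gb);
    }

    if (it >= burn_in) {
      const int post = it - burn_in;
      if (estimate == 1 && post % thin == 0) {
        for (int d = 0; d < n_docs; ++d)
          for (int j = 0; j < K; ++j)
            theta_acc[(size_t)d * K + j] +=
              (nd_k[(size_t)d * K + j] + alpha) / (nd[d] + K * alpha);
        for (int w = 0; w < n_words; ++w)
          for (int j = 0; j < K; ++j)
            phi_acc[(size_t)w * K + j] +=
              (nw_k[(size_t)w * K + j] + beta) * denom[j];
        n_acc++;
      }
      if (trace > 0 && post % trace == 0) traces.push_back(clone(z));
    }
  }

  NumericMatrix theta(n_docs, K);
  NumericMatrix phi(K, n_words);
  IntegerMatrix counts_ck(n_docs, K);
  IntegerMatrix counts_kg(K, n_words);
  for (int d = 0; d < n_docs; ++d)
    for (int j = 0; j < K; ++j)
      counts_ck(d, j) = nd_k[(size_t)d * K + j];
  for (int w = 0; w < n_words; ++w)
    for (int j = 0; j < K; ++j)
      counts_kg(j, w) = nw_k[(size_t)w * K + j];

  if (estimate == 1 && n_acc > 0) {
    for (int d = 0; d < n_docs; ++d)
      for (int j = 0; j < K; ++j)
        theta(d, j) = theta_acc[(size_t)d * K + j] / n_acc;
    for (int w = 0; w < n_words; ++w)
      for (int j = 0; j < K; ++j)
        phi(j, w) = phi_acc[(size_t)w * K + j] / n_acc;
  } else {
    for (int d = 0; d < n_docs; ++d)
      for (int j = 0; j < K; ++j)
        theta(d, j) = (nd_k[(size_t)d * K + j] + alpha) / (nd[d] + K * alpha);
    for (int w = 0; w < n_words; ++w)
      for (int j = 0; j < K; ++j)
        phi(j, w) = (nw_k[(size_t)w * K + j] + beta) / (nk[j] + Gb);
  }

  List out = List::create(
    _["theta"] = theta, _["phi"] = phi,
    _["counts_ck"] = counts_ck, _["counts_kg"] = counts_kg,
    _["assignments"] = z);
  if (trace > 0) {
    IntegerMatrix tr(traces.size(), T);
    for (size_t i = 0; i < traces.size(); ++i)
      for (int t = 0; t < T; ++t) tr(i, t) = traces[i][t];
    out["trace"] = tr;
  }
  return out;
}
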