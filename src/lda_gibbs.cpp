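#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Tokens are given as parallel 0-based
// doc/word index vectors. Uses R's RNG so results are reproducible under
// set.seed(). Posterior-mean estimates of theta (D x K) and beta (K x W) are
// averaged over the kept draws; the per-iteration collapsed joint
// log p(w, z | alpha, gamma) is returned as a trace.
// [[Rcpp::export]]
List cpp_lda_gibbs(IntegerVector doc, IntegerVector word,
                   int D, int W, int K,
                   double alpha, double gamma,
                   int n_burnin, int n_keep) {
  const int N = doc.size();
  std::vector<int> z(N);
  // nwk is W x K token-contiguous (all topics of a word adjacent in memory)
  std::vector<double> ndk((size_t)D * K, 0.0), nwk((size_t)W * K, 0.0),
      nk(K, 0.0), nd(D, 0.0), invden(K, 0.0);

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk[(size_t)doc[i] * K + k] += 1.0;
    nwk[(size_t)word[i] * K + k] += 1.0;
    nk[k] += 1.0;
    nd[doc[i]] += 1.0;
  }

  const int n_iter = n_burnin + n_keep;
  NumericVector loglik(n_iter);
  NumericMatrix theta_sum(D, K), beta_sum(K, W);
  std::vector<double> p(K);
  const double Wg = W * gamma, Ka = K * alpha;
  for (int k = 0; k < K; ++k) invden[k] = 1.0 / (nk[k] + Wg);

  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      const int k = z[i];
      double* nd_k = &ndk[(size_t)d * K];
      double* nw_k = &nwk[(size_t)w * K];
      nd_k[k] -= 1.0;
      nw_k[k] -= 1.0;
      nk[k] -= 1.0;
      invden[k] = 1.0 / (nk[k] + Wg);
      double tot = 0.0;
      for (int kk = 0; kk < K; ++kk) {
        p[kk] = (nd_k[kk] + alpha) * (nw_k[kk] + gamma) * invden[kk];
        tot += p[kk];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double acc = p[0];
      while (u > acc && knew < K - 1) acc += p[++knew];
      z[i] = knew;
      nd_k[knew] += 1.0;
      nw_k[knew] += 1.0;
      nk[knew] += 1.0;
      invden[knew] = 1.0 / (nk[knew] + Wg);
    }
    // collapsed joint log-likelihood (up to no constants): p(w | z) p(z)
    double ll = 0.0;
    for (int k = 0; k < K; ++k) {
      ll += R::lgammafn(Wg) - W * R::lgammafn(gamma) - R::lgammafn(nk[k] + Wg);
      for (int w = 0; w < W; ++w)
        ll += R::lgammafn(nwk[(size_t)w * K + k] + gamma);
    }
    for (int d = 0; d < D; ++d) {
      ll += R::lgammafn(Ka) - K * R::lgammafn(alpha) - R::lgammafn(nd[d] + Ka);
      for (int k = 0; k < K; ++k)
        ll += R::lgammafn(ndk[(size_t)d * K + k] + alpha);
    }
    loglik[it] = ll;

    if (it >= n_burnin) {
      for (int d = 0; d < D; ++d)
        for (int k = 0; k < K; ++k)
          theta_sum(d, k) += (ndk[(size_t)d * K + k] + alpha) / (nd[d] + Ka);
      for (int k = 0; k < K; ++k)
        for (int w = 0; w < W; ++w)
          beta_sum(k, w) += (nwk[(size_t)w * K + k] + gamma) / (nk[k] + Wg);
    }
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
  }

  const double denom = n_keep > 0 ? (double)n_keep : 1.0;
  for (int d = 0; d < D; ++d)
    for (int k = 0; k < K; ++k) theta_sum(d, k) /= denom;
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < W; ++w) beta_sum(k, w) /= denom;

  return List::create(_["theta_hat"] = theta_sum, _["beta_hat"] = beta_sum,
                      _["loglik"] = loglik, _["z"] = IntegerVector(z.begin(), z.end()));
}

// Fold-in Gibbs for one held-out document: beta is frozen, only the document's
// topic counts move. Returns the document mixture theta averaged over the
// second half of the sweeps.
// [[Rcpp::export]]
NumericVector cpp_lda_foldin(IntegerVector word, NumericMatrix beta,
                             double alpha, int n_inner) {
  const int N = word.size(), K = beta.nrow();
  std::vector<int> z(N);
  std::vector<double> ndk(K, 0.0), p(K);
  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[i] = k;
    ndk[k] += 1.0;
  }
  NumericVector theta(K);
  int n_avg = 0;
  const int half = n_inner / 2;
  for (int it = 0; it < n_inner; ++it) {
    for (int i = 0; i < N; ++i) {
      const int w = word[i];
      ndk[z[i]] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        p[k] = (ndk[k] + alpha) * beta(k, w);
        tot += p[k];
      }
      double u = unif_rand() * tot;
      int knew = 0;
      double acc = p[0];
      while (u > acc && knew < K - 1) acc += p[++knew];
      z[i] = knew;
      ndk[knew] += 1.0;
    }
    if (it >= half) {
      for (int k = 0; k < K; ++k) theta[k] += (ndk[k] + alpha) / (N + K * alpha);
      ++n_avg;
    }
  }
  for (int k = 0; k < K; ++k) theta[k] /= (n_avg > 0 ? n_avg : 1);
  return theta;
}
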