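#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA with fixed symmetric priors, plus the
// left-to-right sequential estimator of held-out log-likelihood
// (Wallach et al. 2009, algorithm for "left-to-right" evaluation).
// Randomness comes from a private mt19937 stream seeded explicitly, so a
// given (corpus, config, seed) is bit-reproducible and independent of R's
// global RNG state.

static inline int sample_discrete(const std::vector<double> &w, double total,
                                  std::mt19937 &rng) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  double u = unif(rng) * total, acc = 0.0;
  const int K = w.size();
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// docs: list of integer vectors of 0-based word ids.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int V, int T, double alpha, double beta,
                   int iterations, int seed) {
  const int D = docs.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_int_distribution<int> topic_unif(0, T - 1);

  std::vector<std::vector<int>> w(D), z(D);
  IntegerMatrix nTW(T, V), nDT(D, T);
  std::vector<int> nT(T, 0);

  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    w[d].assign(dv.begin(), dv.end());
    z[d].resize(w[d].size());
    for (size_t n = 0; n < w[d].size(); ++n) {
      int t = topic_unif(rng);
      z[d][n] = t;
      ++nTW(t, w[d][n]); ++nDT(d, t); ++nT[t];
    }
  }

  const double Vbeta = V * beta;
  std::vector<double> p(T);
  for (int it = 0; it < iterations; ++it) {
    for (int d = 0; d < D; ++d) {
      const size_t Nd = w[d].size();
      for (size_t n = 0; n < Nd; ++n) {
        const int wi = w[d][n], zi = z[d][n];
        --nTW(zi, wi); --nDT(d, zi); --nT[zi];
        double total = 0.0;
        for (int t = 0; t < T; ++t) {
          p[t] = (nTW(t, wi) + beta) / (nT[t] + Vbeta) * (nDT(d, t) + alpha);
          total += p[t];
        }
        const int t = sample_discrete(p, total, rng);
        z[d][n] = t;
        ++nTW(t, wi); ++nDT(d, t); ++nT[t];
      }
    }
    if (it % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["topic_word_counts"] = nTW,
                      _["doc_topic_counts"] = nDT,
                      _["topic_totals"] = wrap(nT));
}

// phi: T x V topic-word probabilities (rows sum to 1).
// docs: held-out documents, 0-based in-vocabulary word ids only.
// Returns the summed natural-log likelihood and token count.
// [[Rcpp::export]]
List left_to_right_cpp(List docs, NumericMatrix phi, double alpha,
                       int particles, int seed) {
  const int T = phi.nrow();
  const int D = docs.size();
  std::mt19937 rng(static_cast<uint32_t>(seed));
  const double Talpha = T * alpha;

  double total_ll = 0.0;
  long n_tokens = 0;
  std::vector<double> p(T);

  for (int d = 0; d < D; ++d) {
    IntegerVector dv = docs[d];
    const int Nd = dv.size();
    if (Nd == 0) continue;
    n_tokens += Nd;
    // per-particle topic assignments and doc-topic counts
    std::vector<std::vector<int>> z(particles, std::vector<int>(Nd, 0));
    std::vector<std::vector<int>> cnt(particles, std::vector<int>(T, 0));
    std::vector<double> pn(Nd, 0.0);

    for (int n = 0; n < Nd; ++n) {
      const int wn = dv[n];
      double mean_p = 0.0;
      for (int r = 0; r < particles; ++r) {
        // resample assignments of preceding positions
        for (int m = 0; m < n; ++m) {
          const int wm = dv[m], zm = z[r][m];
          --cnt[r][zm];
          double tot = 0.0;
          for (int t = 0; t < T; ++t) {
            p[t] = (cnt[r][t] + alpha) * phi(t, wm);
            tot += p[t];
          }
          const int t = sample_discrete(p, tot, rng);
          z[r][m] = t; ++cnt[r][t];
        }
        // predictive probability of word n under this particle
        double tot = 0.0;
        for (int t = 0; t < T; ++t) {
          p[t] = (cnt[r][t] + alpha) / (n + Talpha) * phi(t, wn);
          tot += p[t];
        }
        mean_p += tot;
        // sample and keep the assignment of word n
        const int t = sample_discrete(p, tot, rng);
        z[r][n] = t; ++cnt[r][t];
      }
      pn[n] = mean_p / particles;
    }
    for (int n = 0; n < Nd; ++n) total_ll += std::log(pn[n]);
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["total_loglik"] = total_ll,
                      _["n_tokens"] = (double)n_tokens);
}
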