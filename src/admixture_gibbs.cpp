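#include <Rcpp.h>
using namespace Rcpp;

// Two-cluster Bayesian admixture Gibbs sampler over diploid biallelic
// dosage genotypes (rows = individuals, cols = loci, NA = missing).
//
// Model (K = 2, admixture):
//   z_{ilc} | q_i, p        ~ Cat(q_i1 * f, q_i2 * f)   per allele copy
//   p_{kl}  | z, genotypes  ~ Beta(lambda + nA, lambda + nB)
//   q_i     | z, alpha      ~ Dirichlet(alpha + m_i1, alpha + m_i2)
//   alpha                   ~ Uniform(0, alpha_max), Metropolis random walk
//
// Genotypes are A-dosages, so a genotype g contributes g A-copies and
// (2 - g) B-copies; each copy carries its own origin indicator. Uses R's
// RNG, so results are reproducible under set.seed().
//
// Returns the per-individual posterior mean membership in cluster 1 over
// post-burn-in sweeps, per-batch means (for Monte Carlo SEs), and the
// posterior mean of alpha.

// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix geno, int burn_in, int reps,
                     double lambda, double alpha_init,
                     double alpha_proposal_sd, double alpha_max,
                     bool update_alpha = false, int n_batches = 20) {
  const int N = geno.nrow();
  const int L = geno.ncol();
  const int K = 2;

  // per-copy origin counts: mA[k][l] = A copies assigned to k at locus l
  std::vector<double> nA(K * L), nB(K * L);
  NumericMatrix q(N, K);
  NumericVector p1(L);  // p_{1l}; p_{2l} kept separately
  NumericVector p2(L);
  std::vector<double> m(N * K);  // copy-origin counts per individual

  double alpha = alpha_init;

  // init: random memberships, frequencies from prior mean
  for (int i = 0; i < N; ++i) {
    double u = R::runif(0.0, 1.0);
    q(i, 0) = u;
    q(i, 1) = 1.0 - u;
  }
  for (int l = 0; l < L; ++l) {
    p1[l] = R::rbeta(lambda, lambda);
    p2[l] = R::rbeta(lambda, lambda);
  }

  NumericMatrix q_mean(N, K);
  int batch_len = std::max(1, reps / n_batches);
  int real_batches = (reps + batch_len - 1) / batch_len;
  NumericMatrix batch_mean(real_batches, N);  // cluster-1 membership only
  double alpha_sum = 0.0;
  int kept = 0;

  const int total = burn_in + reps;
  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(nA.begin(), nA.end(), 0.0);
    std::fill(nB.begin(), nB.end(), 0.0);
    std::fill(m.begin(), m.end(), 0.0);

    // --- sample allele-copy origins z, accumulate counts
    for (int i = 0; i < N; ++i) {
      const double qi1 = q(i, 0), qi2 = q(i, 1);
      for (int l = 0; l < L; ++l) {
        int g = geno(i, l);
        if (g == NA_INTEGER) continue;
        // A copies
        for (int c = 0; c < g; ++c) {
          double w1 = qi1 * p1[l], w2 = qi2 * p2[l];
          double s = w1 + w2;
          int k = (s <= 0.0) ? (R::unif_rand() < 0.5 ? 0 : 1)
                             : (R::unif_rand() * s < w1 ? 0 : 1);
          nA[k * L + l] += 1.0;
          m[i * K + k] += 1.0;
        }
        // B copies
        for (int c = 0; c < 2 - g; ++c) {
          double w1 = qi1 * (1.0 - p1[l]), w2 = qi2 * (1.0 - p2[l]);
          double s = w1 + w2;
          int k = (s <= 0.0) ? (R::unif_rand() < 0.5 ? 0 : 1)
                             : (R::unif_rand() * s < w1 ? 0 : 1);
          nB[k * L + l] += 1.0;
          m[i * K + k] += 1.0;
        }
      }
    }

    // --- sample cluster allele frequencies
    for (int l = 0; l < L; ++l) {
      p1[l] = R::rbeta(lambda + nA[0 * L + l], lambda + nB[0 * L + l]);
      p2[l] = R::rbeta(lambda + nA[1 * L + l], lambda + nB[1 * L + l]);
    }

    // --- sample admixture proportions
    for (int i = 0; i < N; ++i) {
      double g1 = R::rgamma(alpha + m[i * K + 0], 1.0);
      double g2 = R::rgamma(alpha + m[i * K + 1], 1.0);
      double s = g1 + g2;
      if (s <= 0.0) { g1 = 0.5; g2 = 0.5; s = 1.0; }
      q(i, 0) = g1 / s;
      q(i, 1) = g2 / s;
    }

    // --- optional Metropolis update for alpha (uniform prior on (0, alpha_max))
    double alpha_new = update_alpha
      ? alpha + R::norm_rand() * alpha_proposal_sd : -1.0;
    if (update_alpha && alpha_new > 0.0 && alpha_new < alpha_max) {
      // log-likelihood of q under symmetric Dirichlet(alpha), K = 2
      double sum_log_q = 0.0;
      for (int i = 0; i < N; ++i) {
        double q1 = std::max(q(i, 0), 1e-300);
        double q2 = std::max(q(i, 1), 1e-300);
        sum_log_q += std::log(q1) + std::log(q2);
      }
      double ll_new = N * (R::lgammafn(K * alpha_new) - K * R::lgammafn(alpha_new))
                      + (alpha_new - 1.0) * sum_log_q;
      double ll_old = N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
                      + (alpha - 1.0) * sum_log_q;
      if (std::log(R::unif_rand()) < ll_new - ll_old) alpha = alpha_new;
    }

    // --- accumulate posterior means after burn-in
    if (sweep >= burn_in) {
      int t = sweep - burn_in;
      int b = t / batch_len;
      if (b >= real_batches) b = real_batches - 1;
      for (int i = 0; i < N; ++i) {
        q_mean(i, 0) += q(i, 0);
        q_mean(i, 1) += q(i, 1);
        batch_mean(b, i) += q(i, 0);
      }
      alpha_sum += alpha;
      ++kept;
    }

    if (sweep % 512 == 0) Rcpp::checkUserInterrupt();
  }

  for (int i = 0; i < N; ++i) {
    q_mean(i, 0) /= kept;
    q_mean(i, 1) /= kept;
  }
  for (int b = 0; b < real_batches; ++b) {
    int len = std::min(batch_len, reps - b * batch_len);
    for (int i = 0; i < N; ++i) batch_mean(b, i) /= len;
  }

  return List::create(_["q_mean"] = q_mean,
                      _["batch_mean_cluster1"] = batch_mean,
                      _["alpha_mean"] = alpha_sum / kept,
                      _["sweeps_kept"] = kept);
}
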