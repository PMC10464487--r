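#include <Rcpp.h>
using namespace Rcpp;

// Draw from Dirichlet(shape) using gamma variates (R's RNG, so results are
// reproducible under set.seed()).
static void rdirichlet_inplace(std::vector<double>& shape,
                               std::vector<double>& out) {
  double s = 0.0;
  for (size_t i = 0; i < shape.size(); ++i) {
    double g = R::rgamma(shape[i], 1.0);
    out[i] = g;
    s += g;
  }
  if (s <= 0.0) {  // numerically degenerate: fall back to normalized shape
    s = 0.0;
    for (size_t i = 0; i < shape.size(); ++i) s += shape[i];
    for (size_t i = 0; i < shape.size(); ++i) out[i] = shape[i] / s;
    return;
  }
  for (size_t i = 0; i < out.size(); ++i) out[i] /= s;
}

static int sample_categorical(const std::vector<double>& w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = R::unif_rand() * tot;
  double acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Gibbs sampler for the no-linkage admixture model with independent allele
// frequencies. geno is n x (2L) of 0-based allele indices (-1 = missing).
// Returns posterior-mean Q and P, the post-burn-in log-likelihood trace and
// the alpha trace.
// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs(IntegerMatrix geno, IntegerVector n_alleles, int K,
                     int burnin, int iters, double alpha_init, double lambda,
                     bool locprior, IntegerVector pop_index, int n_pops,
                     double locprior_r, double alpha_prop_sd,
                     bool update_alpha) {
  RNGScope scope;
  const int n = geno.nrow();
  const int L = n_alleles.size();
  const int n_keep = iters - burnin;

  // allele-frequency state: P[l] is K x A_l (row-major by cluster)
  std::vector<std::vector<double>> P(L), Psum(L), Pcnt(L);
  for (int l = 0; l < L; ++l) {
    P[l].assign(K * n_alleles[l], 1.0 / n_alleles[l]);
    Psum[l].assign(K * n_alleles[l], 0.0);
    Pcnt[l].assign(K * n_alleles[l], 0.0);
  }
  std::vector<double> Q(n * K, 1.0 / K), Qsum(n * K, 0.0);
  std::vector<int> Z(n * 2 * L, 0);
  std::vector<double> w(K), shape(0), draw(0);
  std::vector<double> zcount(n * K, 0.0);
  std::vector<double> popcount(n_pops * K, 0.0);
  double alpha = alpha_init;
  NumericVector loglik(n_keep), alpha_trace(n_keep);

  for (int it = 0; it < iters; ++it) {
    // (i) sample cluster of origin Z for every allele copy
    std::fill(zcount.begin(), zcount.end(), 0.0);
    for (int l = 0; l < L; ++l)
      std::fill(Pcnt[l].begin(), Pcnt[l].end(), 0.0);
    if (locprior) std::fill(popcount.begin(), popcount.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int c = 0; c < 2; ++c) {
          int a = geno(i, 2 * l + c);
          if (a < 0) continue;
          for (int k = 0; k < K; ++k)
            w[k] = Q[i * K + k] * P[l][k * n_alleles[l] + a];
          int z = sample_categorical(w, K);
          Z[(i * L + l) * 2 + c] = z;
          zcount[i * K + z] += 1.0;
          Pcnt[l][z * n_alleles[l] + a] += 1.0;
          if (locprior) popcount[pop_index[i] * K + z] += 1.0;
        }
      }
    }
    // (ii) P | Z ~ Dirichlet(lambda + counts)
    for (int l = 0; l < L; ++l) {
      int A = n_alleles[l];
      shape.assign(A, 0.0);
      draw.assign(A, 0.0);
      for (int k = 0; k < K; ++k) {
        for (int a = 0; a < A; ++a)
          shape[a] = lambda + Pcnt[l][k * A + a];
        rdirichlet_inplace(shape, draw);
        for (int a = 0; a < A; ++a) P[l][k * A + a] = draw[a];
      }
    }
    // (iii) Q | Z ~ Dirichlet(prior + counts); with the location prior the
    // symmetric alpha is augmented by r times the population's current
    // assignment proportions.
    shape.assign(K, 0.0);
    draw.assign(K, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) {
        double prior = alpha;
        if (locprior) {
          double tot = 0.0;
          for (int kk = 0; kk < K; ++kk)
            tot += popcount[pop_index[i] * K + kk];
          if (tot > 0.0)
            prior += locprior_r * popcount[pop_index[i] * K + k] / tot;
        }
        shape[k] = prior + zcount[i * K + k];
      }
      rdirichlet_inplace(shape, draw);
      for (int k = 0; k < K; ++k) {
        double q = draw[k];
        if (q < 1e-12) q = 1e-12;  // keep log densities finite
        Q[i * K + k] = q;
      }
    }
    // (iv) Metropolis random walk on log(alpha), uniform prior on (0, 10]
    if (update_alpha && K > 1) {
      double la = std::log(alpha);
      double la_new = la + alpha_prop_sd * R::norm_rand();
      double alpha_new = std::exp(la_new);
      if (alpha_new > 0.0 && alpha_new <= 10.0) {
        double sum_logq = 0.0;
        for (int i = 0; i < n; ++i)
          for (int k = 0; k < K; ++k) sum_logq += std::log(Q[i * K + k]);
        double ll_old = n * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha))
          + (alpha - 1.0) * sum_logq;
        double ll_new = n * (R::lgammafn(K * alpha_new)
          - K * R::lgammafn(alpha_new)) + (alpha_new - 1.0) * sum_logq;
        // log-scale proposal: Jacobian term log(alpha_new) - log(alpha)
        double log_acc = ll_new - ll_old + la_new - la;
        if (std::log(R::unif_rand()) < log_acc) alpha = alpha_new;
      }
    }
    // record post-burn-in state
    if (it >= burnin) {
      int t = it - burnin;
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l)
          for (int c = 0; c < 2; ++c) {
            int a = geno(i, 2 * l + c);
            if (a < 0) continue;
            double m = 0.0;
            for (int k = 0; k < K; ++k)
              m += Q[i * K + k] * P[l][k * n_alleles[l] + a];
            ll += std::log(m);
          }
      loglik[t] = ll;
      alpha_trace[t] = alpha;
      for (int i = 0; i < n * K; ++i) Qsum[i] += Q[i];
      for (int l = 0; l < L; ++l)
        for (size_t j = 0; j < P[l].size(); ++j) Psum[l][j] += P[l][j];
    }
  }

  NumericMatrix Qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qmean(i, k) = Qsum[i * K + k] / n_keep;
  List Pmean(L);
  for (int l = 0; l < L; ++l) {
    int A = n_alleles[l];
    NumericMatrix pm(K, A);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < A; ++a)
        pm(k, a) = Psum[l][k * A + a] / n_keep;
    Pmean[l] = pm;
  }
  return List::create(_["Q"] = Qmean, _["P"] = Pmean,
                      _["loglik"] = loglik, _["alpha_trace"] = alpha_trace);
}
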