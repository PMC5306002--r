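// Gibbs sampler for the Bayesian admixture (mixed-ancestry) clustering
// model with independent Dirichlet(lambda) allele frequencies:
//   Z (origin of each allele copy) | Q, P   categorical
//   P (cluster allele frequencies) | Z      Dirichlet(lambda + counts)
//   Q (individual memberships)     | Z      Dirichlet(alpha + counts)
//   alpha                                   Metropolis random walk,
//                                           Uniform(0, alpha_max) prior
// With the location prior, the Dirichlet prior on Q_i becomes
// r * gamma_{loc(i)} where gamma_l are per-location mean memberships
// (Dirichlet-updated from the location's copy counts) and r = K.
#include <Rcpp.h>
using namespace Rcpp;

static void rdirichlet_inplace(std::vector<double> &out,
                               const std::vector<double> &alpha) {
  double s = 0.0;
  for (size_t k = 0; k < alpha.size(); ++k) {
    out[k] = R::rgamma(alpha[k], 1.0);
    if (out[k] < 1e-300) out[k] = 1e-300;
    s += out[k];
  }
  for (size_t k = 0; k < alpha.size(); ++k) out[k] /= s;
}

// log Dirichlet(alpha * 1_K) density of q
static double ldir_sym(const std::vector<double> &q, int n, int i0, int K,
                       double alpha) {
  double s = R::lgammafn(K * alpha) - K * R::lgammafn(alpha);
  for (int k = 0; k < K; ++k)
    s += (alpha - 1.0) * std::log(q[(size_t)i0 * K + k]);
  (void)n;
  return s;
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix X, IntegerVector J, int K,
                         int iters, int burnin, double lambda,
                         double alpha_init, double alpha_max,
                         double alpha_prop_frac,
                         IntegerVector loc, bool locprior) {
  const int n = X.nrow();
  const int L = J.size();            // loci; X has 2L columns
  const int nloc = locprior ? (max(loc) + 1) : 0;
  const double r_lp = (double)K;     // location-prior strength

  // state
  std::vector<int> Z((size_t)n * L * 2, 0);
  std::vector<double> P; // per locus: K x J[l], ragged, offsets
  std::vector<int> Poff(L + 1, 0);
  for (int l = 0; l < L; ++l) Poff[l + 1] = Poff[l] + K * J[l];
  P.assign(Poff[L], 0.0);
  std::vector<double> Q((size_t)n * K, 1.0 / K);
  std::vector<double> gamma_l((size_t)std::max(nloc, 1) * K, 1.0 / K);
  double alpha = alpha_init;

  // initialize Z uniformly, then P from counts
  for (size_t t = 0; t < Z.size(); ++t)
    Z[t] = (int)std::floor(unif_rand() * K);

  std::vector<double> Qsum((size_t)n * K, 0.0);
  std::vector<double> Psum(Poff[L], 0.0);
  std::vector<double> lltrace(iters, 0.0);
  std::vector<double> atrace(iters, 0.0);
  int kept = 0;

  std::vector<double> prob(K), dirpar(std::max(K, 2));
  std::vector<double> cnt;     // scratch counts
  std::vector<double> mik((size_t)n * K, 0.0);

  for (int it = 0; it < iters; ++it) {
    // --- update P per locus from Z counts ---
    for (int l = 0; l < L; ++l) {
      const int Jl = J[l];
      cnt.assign((size_t)K * Jl, lambda);
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < 2; ++c) {
          int x = X(i, 2 * l + c);
          if (x <= 0) continue;
          int z = Z[((size_t)i * L + l) * 2 + c];
          cnt[(size_t)z * Jl + (x - 1)] += 1.0;
        }
      }
      for (int k = 0; k < K; ++k) {
        double s = 0.0;
        for (int j = 0; j < Jl; ++j) {
          double g = R::rgamma(cnt[(size_t)k * Jl + j], 1.0);
          if (g < 1e-300) g = 1e-300;
          P[Poff[l] + (size_t)k * Jl + j] = g;
          s += g;
        }
        for (int j = 0; j < Jl; ++j) P[Poff[l] + (size_t)k * Jl + j] /= s;
      }
    }

    // --- update Z | Q, P and accumulate per-individual counts ---
    std::fill(mik.begin(), mik.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        const int Jl = J[l];
        for (int c = 0; c < 2; ++c) {
          int x = X(i, 2 * l + c);
          if (x <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q[(size_t)i * K + k] *
                      P[Poff[l] + (size_t)k * Jl + (x - 1)];
            s += prob[k];
          }
          double u = unif_rand() * s, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { z = k; break; } }
          Z[((size_t)i * L + l) * 2 + c] = z;
          mik[(size_t)i * K + z] += 1.0;
        }
      }
    }

    // --- update location hyper-proportions (locprior) ---
    if (locprior) {
      for (int g = 0; g < nloc; ++g) {
        std::vector<double> par(K, 1.0);
        for (int i = 0; i < n; ++i)
          if (loc[i] == g)
            for (int k = 0; k < K; ++k) par[k] += mik[(size_t)i * K + k];
        std::vector<double> gv(K);
        rdirichlet_inplace(gv, par);
        for (int k = 0; k < K; ++k) gamma_l[(size_t)g * K + k] = gv[k];
      }
    }

    // --- update Q | Z ---
    for (int i = 0; i < n; ++i) {
      std::vector<double> par(K);
      for (int k = 0; k < K; ++k) {
        double prior = locprior ? r_lp * gamma_l[(size_t)loc[i] * K + k]
                                : alpha;
        par[k] = prior + mik[(size_t)i * K + k];
      }
      std::vector<double> qv(K);
      rdirichlet_inplace(qv, par);
      for (int k = 0; k < K; ++k) Q[(size_t)i * K + k] = qv[k];
    }

    // --- Metropolis update of alpha (no locprior; K > 1) ---
    if (!locprior && K > 1) {
      double prop = alpha + norm_rand() * alpha_prop_frac * alpha;
      if (prop > 0 && prop < alpha_max) {
        double lr = 0.0;
        for (int i = 0; i < n; ++i)
          lr += ldir_sym(Q, n, i, K, prop) - ldir_sym(Q, n, i, K, alpha);
        if (std::log(unif_rand()) < lr) alpha = prop;
      }
    }

    // --- data log-likelihood at current (P, Q) ---
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < L; ++l) {
        const int Jl = J[l];
        for (int c = 0; c < 2; ++c) {
          int x = X(i, 2 * l + c);
          if (x <= 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += Q[(size_t)i * K + k] *
                 P[Poff[l] + (size_t)k * Jl + (x - 1)];
          ll += std::log(std::max(s, 1e-300));
        }
      }
    lltrace[it] = ll;
    atrace[it] = alpha;

    if (it >= burnin) {
      ++kept;
      for (size_t t = 0; t < Qsum.size(); ++t) Qsum[t] += Q[t];
      for (size_t t = 0; t < Psum.size(); ++t) Psum[t] += P[t];
    }
  }

  NumericMatrix Qm(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qm(i, k) = Qsum[(size_t)i * K + k] / kept;
  List Pl(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix Pm(K, J[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < J[l]; ++j)
        Pm(k, j) = Psum[Poff[l] + (size_t)k * J[l] + j] / kept;
    Pl[l] = Pm;
  }
  return List::create(_["Q"] = Qm, _["P"] = Pl,
                      _["loglik"] = NumericVector(lltrace.begin(), lltrace.end()),
                      _["alpha"] = NumericVector(atrace.begin(), atrace.end()));
}
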