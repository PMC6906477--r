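// Single-site Gibbs sampler for the four-distribution SNP-effect mixture
// model with heterogeneous residual weights:
//   y = 1 mu + sum_c X_c g_c + e,   e ~ N(0, D sigma2_e),
//   g_cj | class k ~ N(0, sigma4_c * ratio_k),  ratios fixed
//   (1/1000, 1/100, 1/10, 1); class probs pi_c ~ Dirichlet(counts);
//   sigma4_c and sigma2_e carry scaled inverse chi-square priors.
// Uses R's RNG throughout, so chains are byte-identical given set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvchisq(double df, double scale_sum) {
  // draw from (scale_sum) / chisq_df
  return scale_sum / R::rchisq(df);
}

static void rdirichlet_inplace(const arma::vec& alpha, arma::vec& out) {
  double tot = 0.0;
  for (arma::uword k = 0; k < alpha.n_elem; ++k) {
    out[k] = R::rgamma(alpha[k], 1.0);
    tot += out[k];
  }
  out /= tot;
}

// [[Rcpp::export(name = ".gibbs_mixture_cpp")]]
List gibbs_mixture(const arma::vec& y, const arma::vec& weights,
                   const List& Xlist, const arma::vec& dirichlet,
                   const arma::vec& ratios, const arma::mat& pi_init,
                   double df_sigma, const arma::vec& sigma4_init,
                   const arma::vec& sigma4_scale, double sigma_e_init,
                   double sigma_e_scale, double mu_init, int n_iter,
                   int burn_in, int thin, bool fix_mu, bool fix_pi,
                   bool fix_sigma4, bool fix_sigma_e, bool random_order) {
  const int n = y.n_elem;
  const int ncomp = Xlist.size();
  std::vector<arma::mat> X(ncomp);
  std::vector<arma::vec> g(ncomp), xtwx(ncomp);
  std::vector<arma::uvec> cls(ncomp);
  arma::vec sigma4 = sigma4_init;
  std::vector<arma::vec> pi(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    X[c] = as<arma::mat>(Xlist[c]);
    const int M = X[c].n_cols;
    g[c] = arma::zeros(M);
    cls[c] = arma::uvec(M, arma::fill::zeros);
    xtwx[c] = arma::vec(M);
    for (int j = 0; j < M; ++j)
      xtwx[c][j] = arma::accu(weights % arma::square(X[c].col(j)));
    pi[c] = pi_init.row(c).t();
  }
  double mu = mu_init, sigma_e = sigma_e_init;
  arma::vec e = y - mu;  // effects start at zero
  const double sum_w = arma::accu(weights);

  const int n_save = (n_iter - burn_in) / thin;
  arma::vec mu_s(n_save), sigma_e_s(n_save);
  std::vector<arma::mat> g_s(ncomp), pi_s(ncomp), clsfreq(ncomp);
  std::vector<arma::vec> sigma4_s(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    g_s[c] = arma::mat(n_save, X[c].n_cols);
    pi_s[c] = arma::mat(n_save, 4);
    sigma4_s[c] = arma::vec(n_save);
    clsfreq[c] = arma::mat(X[c].n_cols, 4, arma::fill::zeros);
  }

  double logr[4];
  for (int k = 0; k < 4; ++k) logr[k] = std::log(ratios[k]);
  int isave = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (!fix_mu) {
      double mean = arma::accu(weights % (e + mu)) / sum_w;
      double newmu = mean + R::norm_rand() * std::sqrt(sigma_e / sum_w);
      e += mu - newmu;
      mu = newmu;
    }
    for (int c = 0; c < ncomp; ++c) {
      const int M = X[c].n_cols;
      arma::uvec ord(M);
      for (int j = 0; j < M; ++j) ord[j] = j;
      if (random_order)
        for (int j = M - 1; j > 0; --j)
          std::swap(ord[j], ord[(int)(R::unif_rand() * (j + 1))]);
      const double ls4 = std::log(sigma4[c]);
      for (int jj = 0; jj < M; ++jj) {
        const int j = ord[jj];
        const double gj = g[c][j];
        const double xwr =
          arma::accu(weights % X[c].col(j) % e) + xtwx[c][j] * gj;
        const double rhs = xwr / sigma_e;
        double logw[4], prec[4], lmax = -1e300;
        for (int k = 0; k < 4; ++k) {
          const double vk = sigma4[c] * ratios[k];
          prec[k] = xtwx[c][j] / sigma_e + 1.0 / vk;
          logw[k] = std::log(pi[c][k]) - 0.5 * (ls4 + logr[k]) -
            0.5 * std::log(prec[k]) + 0.5 * rhs * rhs / prec[k];
          if (logw[k] > lmax) lmax = logw[k];
        }
        double cum = 0.0, wk[4];
        for (int k = 0; k < 4; ++k) { wk[k] = std::exp(logw[k] - lmax);
                                      cum += wk[k]; }
        double u = R::unif_rand() * cum;
        int k = 0;
        for (; k < 3; ++k) { u -= wk[k]; if (u <= 0) break; }
        cls[c][j] = k;
        const double gnew =
          rhs / prec[k] + R::norm_rand() / std::sqrt(prec[k]);
        if (gnew != gj) e += X[c].col(j) * (gj - gnew);
        g[c][j] = gnew;
      }
      if (!fix_pi) {
        arma::vec alpha = dirichlet;
        for (int j = 0; j < M; ++j) alpha[cls[c][j]] += 1.0;
        rdirichlet_inplace(alpha, pi[c]);
      }
      if (!fix_sigma4) {
        double ssq = 0.0;
        for (int j = 0; j < M; ++j)
          ssq += g[c][j] * g[c][j] / ratios[cls[c][j]];
        sigma4[c] = rinvchisq(df_sigma + M,
                              df_sigma * sigma4_scale[c] + ssq);
      }
    }
    if (!fix_sigma_e) {
      const double sse = arma::accu(weights % arma::square(e));
      sigma_e = rinvchisq(df_sigma + n, df_sigma * sigma_e_scale + sse);
    }
    if (!std::isfinite(mu) || !std::isfinite(sigma_e))
      stop("non-finite sampler state at iteration %d", iter);

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      mu_s[isave] = mu;
      sigma_e_s[isave] = sigma_e;
      for (int c = 0; c < ncomp; ++c) {
        g_s[c].row(isave) = g[c].t();
        pi_s[c].row(isave) = pi[c].t();
        sigma4_s[c][isave] = sigma4[c];
        for (arma::uword j = 0; j < cls[c].n_elem; ++j)
          clsfreq[c](j, cls[c][j]) += 1.0;
      }
      ++isave;
    }
  }
  List comps(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    if (n_save > 0) clsfreq[c] /= (double)n_save;
    comps[c] = List::create(_["effects"] = g_s[c], _["pi"] = pi_s[c],
                            _["sigma4"] = sigma4_s[c],
                            _["classProb"] = clsfreq[c]);
  }
  return List::create(_["mu"] = mu_s, _["sigma_e"] = sigma_e_s,
                      _["components"] = comps);
}
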