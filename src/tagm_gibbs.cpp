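// Collapsed Gibbs sampler for the T-augmented Gaussian mixture (TAGM):
// one Gaussian component per marker-defined compartment with a
// Normal-inverse-Wishart prior (component parameters integrated out
// analytically, giving multivariate-t marginal predictives), plus a fixed
// multivariate-t outlier component. Marker proteins are clamped to their
// compartment; unlabelled proteins have their component allocation z and
// in-mixture indicator phi sampled jointly; the outlier weight eps is
// sampled from its Beta full conditional.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double mvt_logpdf(const arma::vec& x, const arma::vec& mu,
                         const arma::mat& R_upper, double df) {
  const double d = (double)x.n_elem;
  arma::vec z = arma::solve(arma::trimatl(R_upper.t()), x - mu);
  double quad = arma::dot(z, z);
  double logdet = 2.0 * arma::sum(arma::log(R_upper.diag()));
  return lgamma(0.5 * (df + d)) - lgamma(0.5 * df) -
         0.5 * d * std::log(df * M_PI) - 0.5 * logdet -
         0.5 * (df + d) * std::log1p(quad / df);
}

struct Component {
  double n;
  arma::vec sum;        // sum of member profiles
  arma::mat sxx;        // sum of outer products
  bool dirty;
  arma::vec pred_mean;
  arma::mat pred_chol;  // upper Cholesky of the predictive scale
  double pred_df;
};

// [[Rcpp::export(name = ".tagm_gibbs")]]
List tagm_gibbs(const arma::mat& X, const IntegerVector& marker_z, int K,
                const arma::vec& beta0, double lambda0, double nu0,
                const arma::mat& S0, double alpha, double u, double v,
                double kappa, const arma::vec& M, const arma::mat& V,
                int n_iter, int burn_in, int thin) {
  const int n = X.n_rows, d = X.n_cols;
  const arma::mat R_out = arma::chol(V);
  bool jittered = false;

  std::vector<Component> comp(K);
  for (int k = 0; k < K; ++k) {
    comp[k].n = 0.0;
    comp[k].sum = arma::zeros(d);
    comp[k].sxx = arma::zeros(d, d);
    comp[k].dirty = true;
    comp[k].pred_df = 0.0;
  }

  auto refresh = [&](int k) {
    Component& c = comp[k];
    double ln = lambda0 + c.n;
    double nun = nu0 + c.n;
    arma::vec mn = (lambda0 * beta0 + c.sum) / ln;
    arma::mat Sn = S0;
    if (c.n > 0) {
      arma::vec xbar = c.sum / c.n;
      Sn += c.sxx - c.n * (xbar * xbar.t());
      arma::vec dm = xbar - beta0;
      Sn += (lambda0 * c.n / ln) * (dm * dm.t());
    }
    double df = nun - d + 1.0;
    arma::mat scale = Sn * ((ln + 1.0) / (ln * df));
    arma::mat R;
    if (!arma::chol(R, scale)) {
      scale.diag() += 1e-8;
      jittered = true;
      if (!arma::chol(R, scale))
        stop("singular component scale matrix");
    }
    c.pred_mean = mn;
    c.pred_chol = R;
    c.pred_df = df;
    c.dirty = false;
  };
  auto add_to = [&](int k, const arma::vec& x) {
    comp[k].n += 1.0;
    comp[k].sum += x;
    comp[k].sxx += x * x.t();
    comp[k].dirty = true;
  };
  auto remove_from = [&](int k, const arma::vec& x) {
    comp[k].n -= 1.0;
    comp[k].sum -= x;
    comp[k].sxx += -(x * x.t());
    comp[k].dirty = true;
  };

  std::vector<int> unknown;
  std::vector<int> z(n, 0), phi(n, 1);
  int n_markers = 0;
  for (int i = 0; i < n; ++i) {
    arma::vec xi = X.row(i).t();
    if (marker_z[i] > 0) {
      z[i] = marker_z[i] - 1;
      add_to(z[i], xi);
      ++n_markers;
    } else {
      unknown.push_back(i);
    }
  }
  const int nu_n = (int)unknown.size();

  // random initialisation of the unlabelled proteins (all phi = 1)
  for (int j = 0; j < nu_n; ++j) {
    int i = unknown[j];
    int k = (int)std::floor(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    add_to(k, X.row(i).t());
  }
  double eps = u / (u + v);

  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  IntegerMatrix Z_out(n_keep, nu_n), Phi_out(n_keep, nu_n);
  NumericVector nout_trace(n_keep), lj_trace(n_keep);
  arma::vec logw(K + 1);
  int stored = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    double log_joint = 0.0;
    for (int j = 0; j < nu_n; ++j) {
      int i = unknown[j];
      arma::vec xi = X.row(i).t();
      if (phi[i] == 1) remove_from(z[i], xi);

      // comp[].n counts markers plus currently in-mixture unknowns
      double n_in = 0.0;
      for (int k = 0; k < K; ++k) n_in += comp[k].n;

      double denom = std::log(n_in + K * alpha);
      for (int k = 0; k < K; ++k) {
        if (comp[k].dirty) refresh(k);
        logw[k] = std::log1p(-eps) + std::log(comp[k].n + alpha) - denom +
          mvt_logpdf(xi, comp[k].pred_mean, comp[k].pred_chol,
                     comp[k].pred_df);
      }
      logw[K] = std::log(eps) + mvt_logpdf(xi, M, R_out, kappa);

      double mx = logw.max();
      arma::vec w = arma::exp(logw - mx);
      double tot = arma::accu(w);
      double udraw = unif_rand() * tot, acc = 0.0;
      int pick = K;
      for (int k = 0; k <= K; ++k) {
        acc += w[k];
        if (udraw <= acc) { pick = k; break; }
      }
      log_joint += logw[pick];
      if (pick < K) {
        phi[i] = 1;
        z[i] = pick;
        add_to(pick, xi);
      } else {
        phi[i] = 0;
      }
    }

    int n_out = 0;
    for (int j = 0; j < nu_n; ++j) n_out += (phi[unknown[j]] == 0);
    eps = R::rbeta(u + n_out, v + (n - n_out));

    if (iter > burn_in && (iter - burn_in) % thin == 0 && stored < n_keep) {
      for (int j = 0; j < nu_n; ++j) {
        Z_out(stored, j) = z[unknown[j]] + 1;
        Phi_out(stored, j) = phi[unknown[j]];
      }
      nout_trace[stored] = n_out;
      lj_trace[stored] = log_joint;
      ++stored;
    }
  }

  return List::create(_["z"] = Z_out, _["phi"] = Phi_out,
                      _["n_outlier"] = nout_trace,
                      _["log_joint"] = lj_trace,
                      _["n_retained"] = stored,
                      _["jittered"] = jittered);
}
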