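// Per-pair multivariate-normal deviance for the latent growth curve model.
//
// Observations are independent across twin pairs; within a pair the
// covariance is
//   V_g = Zb Sigma_B Zb' + Zw (I_m (x) Sigma_W) Zw' + sigma2 * I,
// where Zb stacks the growth basis rows of both twins (between-pair effects
// are shared), Zw is block-diagonal over the m (<= 2) members of the pair,
// and sigma2 is the occasion-constant residual variance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Either evaluates the -2 log-likelihood at a supplied fixed-effect vector
// (profile = false) or profiles the fixed effects out by GLS
// (profile = true), returning the GLS estimate and its information matrix.
// [[Rcpp::export]]
List lgc_deviance_cpp(List pairs,
                      const arma::mat& sigma_b,
                      const arma::mat& sigma_w,
                      double sigma2,
                      Nullable<NumericVector> beta_,
                      bool profile) {
  const int d = sigma_b.n_rows;
  int p = 0;
  {
    List first = pairs[0];
    arma::mat X0 = first["X"];
    p = X0.n_cols;
  }
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec u(p, arma::fill::zeros);
  double q0 = 0.0, logdet = 0.0, quad = 0.0;
  long ntot = 0;

  arma::vec beta;
  if (!profile) {
    if (beta_.isNull()) stop("beta required when profile = FALSE");
    beta = as<arma::vec>(beta_);
  }

  const int G = pairs.size();
  for (int g = 0; g < G; ++g) {
    List pg = pairs[g];
    arma::mat X = pg["X"];
    arma::vec y = pg["y"];
    arma::mat Zb = pg["zb"];
    arma::mat Zw = pg["zw"];
    const int m = as<int>(pg["m"]);
    const int ng = y.n_elem;

    arma::mat Sw(d * m, d * m, arma::fill::zeros);
    for (int j = 0; j < m; ++j)
      Sw.submat(j * d, j * d, (j + 1) * d - 1, (j + 1) * d - 1) = sigma_w;

    arma::mat V = Zb * sigma_b * Zb.t() + Zw * Sw * Zw.t();
    V.diag() += sigma2;

    arma::mat L;
    if (!arma::chol(L, V, "lower"))
      return List::create(_["ok"] = false);

    logdet += 2.0 * arma::sum(arma::log(L.diag()));
    ntot += ng;

    if (profile) {
      arma::mat Xs = arma::solve(arma::trimatl(L), X);
      arma::vec ys = arma::solve(arma::trimatl(L), y);
      A += Xs.t() * Xs;
      u += Xs.t() * ys;
      q0 += arma::dot(ys, ys);
    } else {
      arma::vec rs = arma::solve(arma::trimatl(L), y - X * beta);
      quad += arma::dot(rs, rs);
    }
  }

  const double log2pi = std::log(2.0 * M_PI);
  if (profile) {
    arma::vec bhat;
    if (!arma::solve(bhat, A, u, arma::solve_opts::likely_sympd))
      return List::create(_["ok"] = false);
    quad = q0 - arma::dot(u, bhat);
    double dev = ntot * log2pi + logdet + quad;
    return List::create(_["ok"] = true, _["deviance"] = dev,
                        _["beta"] = bhat, _["info"] = A,
                        _["n"] = (double)ntot);
  }
  double dev = ntot * log2pi + logdet + quad;
  return List::create(_["ok"] = true, _["deviance"] = dev,
                      _["n"] = (double)ntot);
}
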