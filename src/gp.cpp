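// Squared-exponential Gaussian-process regression: negative log marginal
// likelihood and its analytic gradient in the log-parameters
// (log lengthscale, log signal variance, log noise variance). Hot path of
// ML-II hyperparameter optimisation; the posterior itself is assembled in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static bool chol_with_jitter(arma::mat& L, arma::mat K) {
  double jitter = 0.0;
  const double scale = arma::mean(K.diag());
  for (int attempt = 0; attempt < 6; ++attempt) {
    if (attempt > 0) {
      jitter = (jitter == 0.0) ? 1e-10 * scale : jitter * 100.0;
      K.diag() += jitter;
    }
    if (arma::chol(L, K, "lower")) return true;
  }
  return false;
}

// [[Rcpp::export]]
List gp_nll_grad_cpp(NumericVector theta, NumericMatrix D2_, NumericVector y_) {
  const int n = y_.size();
  arma::mat D2(D2_.begin(), n, n, false);
  arma::vec y(y_.begin(), n, false);

  const double ell = std::exp(theta[0]);
  const double sf2 = std::exp(theta[1]);
  const double sn2 = std::exp(theta[2]);

  arma::mat Kf = sf2 * arma::exp(-0.5 * D2 / (ell * ell));
  arma::mat K = Kf;
  K.diag() += sn2;

  arma::mat L;
  if (!chol_with_jitter(L, K)) {
    return List::create(_["nll"] = R_PosInf,
                        _["grad"] = NumericVector(3, 0.0));
  }

  arma::vec alpha = arma::solve(arma::trimatu(L.t()),
                                arma::solve(arma::trimatl(L), y));
  double nll = 0.5 * arma::dot(y, alpha) + arma::accu(arma::log(L.diag())) +
               0.5 * n * std::log(2.0 * M_PI);

  // grad_j = 0.5 * accu(A % dK_j) with A = Kinv - alpha alpha'; one fused
  // pass over the matrix instead of materialising the dK_j terms
  arma::mat Kinv(n, n);
  if (!arma::inv_sympd(Kinv, arma::symmatl(L * L.t()))) {
    return List::create(_["nll"] = R_PosInf,
                        _["grad"] = NumericVector(3, 0.0));
  }
  double s_ell = 0.0, s_f = 0.0, tr_A = 0.0;
  const double inv_ell2 = 1.0 / (ell * ell);
  const double* kf = Kf.memptr();
  const double* d2 = D2.memptr();
  const double* ki = Kinv.memptr();
  const double* al = alpha.memptr();
  for (int j = 0; j < n; ++j) {
    const double aj = al[j];
    const size_t off = (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      const double a = ki[off + i] - al[i] * aj;
      const double akf = a * kf[off + i];
      s_f += akf;
      s_ell += akf * d2[off + i];
      if (i == j) tr_A += a;
    }
  }
  NumericVector grad(3);
  grad[0] = 0.5 * s_ell * inv_ell2;
  grad[1] = 0.5 * s_f;
  grad[2] = 0.5 * sn2 * tr_A;

  return List::create(_["nll"] = nll, _["grad"] = grad);
}
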