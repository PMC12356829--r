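// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>

// Fast exact Kalman log-likelihood for one site of the CT state-space model.
// Per-interval discretization: A_d = expm(A*dt), b_d via augmented matrix
// exponential, Q_d = Sinf - A_d Sinf A_d' with Sinf from the continuous
// Lyapunov equation (Sylvester solve). Missing observations (NaN) delete the
// corresponding measurement rows. Returns NA on numerical failure; mirrors
// the reference R implementation (kalman_site) to ~1e-10.
// [[Rcpp::export]]
double cpp_kalman_loglik(const arma::vec& times, const arma::mat& Y,
                         const arma::mat& A, const arma::vec& b,
                         const arma::mat& G, const arma::vec& meas_sd,
                         const arma::vec& init_mean,
                         const arma::mat& init_cov) {
  const int m = A.n_rows, T = times.n_elem;
  const arma::mat GG = G * G.t();
  const bool diag_drift = arma::accu(arma::abs(A - arma::diagmat(A.diag()))) == 0.0;
  arma::mat Sinf;
  arma::vec a = A.diag();
  if (diag_drift) {
    Sinf.set_size(m, m);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < m; ++j) Sinf(i, j) = -GG(i, j) / (a(i) + a(j));
  } else {
    // solves A X + X A' + GG = 0
    if (!arma::syl(Sinf, A, A.t(), GG)) return NA_REAL;
  }

  std::map<double, arma::mat> Acache, Qcache;
  std::map<double, arma::vec> bcache;

  arma::vec x = init_mean;
  arma::mat P = init_cov;
  const arma::vec R = meas_sd % meas_sd;
  double ll = 0.0;
  const double log2pi = std::log(2.0 * M_PI);

  for (int t = 0; t < T; ++t) {
    if (t > 0) {
      const double dt = times(t) - times(t - 1);
      auto it = Acache.find(dt);
      if (it == Acache.end()) {
        arma::mat Ad(m, m, arma::fill::zeros);
        arma::vec bd(m);
        if (diag_drift) {
          for (int i = 0; i < m; ++i) {
            Ad(i, i) = std::exp(a(i) * dt);
            bd(i) = (Ad(i, i) - 1.0) / a(i) * b(i);
          }
        } else {
          Ad = arma::expmat(A * dt);
          arma::mat aug(m + 1, m + 1, arma::fill::zeros);
          aug.submat(0, 0, m - 1, m - 1) = A * dt;
          aug.submat(0, m, m - 1, m) = b * dt;
          arma::mat eaug = arma::expmat(aug);
          bd = eaug.submat(0, m, m - 1, m);
        }
        arma::mat Qd = Sinf - Ad * Sinf * Ad.t();
        Qd = 0.5 * (Qd + Qd.t());
        for (int i = 0; i < m; ++i) if (Qd(i, i) < 0) Qd(i, i) = 0;
        Acache[dt] = Ad; bcache[dt] = bd; Qcache[dt] = Qd;
        it = Acache.find(dt);
      }
      const arma::mat& Ad = it->second;
      x = Ad * x + bcache[dt];
      P = Ad * P * Ad.t() + Qcache[dt];
      P = 0.5 * (P + P.t());
    }
    // measurement update over observed rows
    arma::uvec obs = arma::find_finite(Y.col(t));
    const int k = obs.n_elem;
    if (k > 0) {
      arma::vec v = Y.col(t);
      v = v(obs) - x(obs);
      arma::mat S = P.submat(obs, obs) + arma::diagmat(R(obs));
      arma::mat cS;
      if (!arma::chol(cS, S)) {
        S.diag() += 1e-10;
        if (!arma::chol(cS, S)) return NA_REAL;
      }
      if (cS.diag().min() < 1e-12) return NA_REAL;
      arma::mat cSinv;
      if (!arma::inv(cSinv, arma::trimatu(cS))) return NA_REAL;
      arma::mat Sinv = cSinv * cSinv.t();
      double ldet = 2.0 * arma::accu(arma::log(cS.diag()));
      ll += -0.5 * (k * log2pi + ldet + arma::dot(v, Sinv * v));
      arma::mat K = P.cols(obs) * Sinv;
      x += K * v;
      P -= K * P.rows(obs);
      P = 0.5 * (P + P.t());
    }
    if (!x.is_finite()) return NA_REAL;
  }
  return ll;
}
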