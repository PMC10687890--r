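// Linear-Gaussian state-space recursions shared by all CTMM families.
// The state is d-dimensional (d = 1 for OU, 2 for OUF/IOU); only the first
// state element (position) is observed. Transition matrices and process
// noise are precomputed per step on the R side; slice 0 encodes the prior
// (Phi_0 = 0, Q_0 = P_inf) so the stationary start falls out of the same
// recursion.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Filter several observation columns at once (they share gains, so the
// innovation sequence is a linear operator applied per column; used for
// GLS profiling of the mean: filter the data and a constant-1 regressor).
// Returns innovations E (n x m) and innovation variances S (n). When
// condition_first is true the state is initialised at the first
// observation (diffuse-position treatment for IOU) and row 0 carries no
// likelihood information (S[0] set to NA).
// [[Rcpp::export]]
List kalman_innovations(const arma::mat& Y, const arma::vec& Rt,
                        const arma::cube& Phi, const arma::cube& Q,
                        bool condition_first) {
  const arma::uword n = Y.n_rows, m = Y.n_cols;
  const arma::uword d = Phi.n_rows;
  arma::mat E(n, m, arma::fill::zeros);
  arma::vec S(n, arma::fill::zeros);

  arma::mat M(d, m, arma::fill::zeros);  // state means, one column per series
  arma::mat P(d, d, arma::fill::zeros);

  arma::uword t0 = 0;
  if (condition_first) {
    for (arma::uword j = 0; j < m; ++j) M(0, j) = Y(0, j);
    P = Q.slice(0);  // conditional prior covariance
    S(0) = NA_REAL;
    t0 = 1;
  }

  for (arma::uword t = t0; t < n; ++t) {
    // predict (slice t encodes prior when t == 0 and !condition_first)
    M = Phi.slice(t) * M;
    P = Phi.slice(t) * P * Phi.slice(t).t() + Q.slice(t);
    // update on position
    double s = P(0, 0) + Rt(t);
    S(t) = s;
    arma::rowvec innov = Y.row(t) - M.row(0);
    E.row(t) = innov;
    if (s > 0) {
      arma::vec K = P.col(0) / s;
      M += K * innov;
      P -= K * P.row(0);
    }
  }
  return List::create(_["E"] = E, _["S"] = S);
}

// Fixed-interval (RTS) smoother for one mean-corrected series. obs_flag
// marks timestamps carrying an observation; unflagged times are pure
// prediction points (the interpolation grid). Returns smoothed state
// means (n x d).
// [[Rcpp::export]]
arma::mat kalman_smooth(const arma::vec& y, const LogicalVector& obs_flag,
                        const arma::vec& Rt, const arma::cube& Phi,
                        const arma::cube& Q, bool condition_first) {
  const arma::uword n = y.n_elem;
  const arma::uword d = Phi.n_rows;
  arma::mat mf(d, n), mp(d, n);    // filtered / predicted means
  arma::cube Pf(d, d, n), Pp(d, d, n);

  arma::vec mcur(d, arma::fill::zeros);
  arma::mat Pcur(d, d, arma::fill::zeros);
  arma::uword t0 = 0;
  if (condition_first) {
    mcur(0) = y(0);
    Pcur = Q.slice(0);
    mp.col(0) = mcur; Pp.slice(0) = Pcur;
    mf.col(0) = mcur; Pf.slice(0) = Pcur;
    t0 = 1;
  }

  for (arma::uword t = t0; t < n; ++t) {
    mcur = Phi.slice(t) * mcur;
    Pcur = Phi.slice(t) * Pcur * Phi.slice(t).t() + Q.slice(t);
    mp.col(t) = mcur; Pp.slice(t) = Pcur;
    if (obs_flag[t]) {
      double s = Pcur(0, 0) + Rt(t);
      if (s > 0) {
        arma::vec K = Pcur.col(0) / s;
        mcur += K * (y(t) - mcur(0));
        Pcur -= K * Pcur.row(0);
      }
    }
    mf.col(t) = mcur; Pf.slice(t) = Pcur;
  }

  // backward pass
  arma::mat ms(d, n);
  ms.col(n - 1) = mf.col(n - 1);
  for (arma::uword t = n - 1; t-- > 0;) {
    arma::mat Ppn = Pp.slice(t + 1);
    // guard singular predicted covariance (e.g. zero-noise degenerate step)
    arma::mat Ci;
    bool ok = arma::inv_sympd(Ci, arma::symmatu(Ppn));
    if (!ok) ok = arma::pinv(Ci, Ppn, 1e-12);
    if (ok) {
      arma::mat C = Pf.slice(t) * Phi.slice(t + 1).t() * Ci;
      ms.col(t) = mf.col(t) + C * (ms.col(t + 1) - mp.col(t + 1));
    } else {
      ms.col(t) = mf.col(t);
    }
  }
  return ms.t();
}
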