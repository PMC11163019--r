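// Kalman filter and RTS smoother for the DFA state-space model
//   x_t = x_{t-1} + w_t, w_t ~ N(0, I_m);  x_1 ~ N(x0, I_m)
//   y_t = Z x_t + a + D d_t + v_t, v_t ~ N(0, R)
// Missing observations (NaN in y) are dropped by row-reduction at each
// time step.  Mirrors the reference R implementation (.dfa_kalman_r).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".dfa_kalman_cpp")]]
Rcpp::List dfa_kalman_cpp(const arma::mat& y, const arma::mat& Z,
                          const arma::mat& R, const arma::vec& x0,
                          const arma::vec& a, const arma::mat& Dd,
                          bool has_Dd, bool smooth) {
  const uword S = y.n_rows, T = y.n_cols, m = Z.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  mat xf(m, T, fill::zeros), xp(m, T, fill::zeros);
  cube Vf(m, m, T, fill::zeros), Vp(m, m, T, fill::zeros);
  vec xprev = x0;
  mat Vprev(m, m, fill::zeros);
  const mat Im = eye(m, m);
  double ll = 0.0;
  bool ok = true;

  for (uword t = 0; t < T; ++t) {
    vec xpt = xprev;
    mat Vpt = Vprev + Im;
    uvec o = find_finite(y.col(t));
    if (o.n_elem > 0) {
      mat Zo = Z.rows(o);
      vec yo = y.col(t);
      yo = yo.elem(o) - a.elem(o);
      if (has_Dd) {
        vec ddt = Dd.col(t);
        yo -= ddt.elem(o);
      }
      mat PZ = Vpt * Zo.t();                    // m x k
      mat F = Zo * PZ + R.submat(o, o);
      F = 0.5 * (F + F.t());
      mat cF;
      if (!chol(cF, F)) { ok = false; break; }
      vec innov = yo - Zo * xpt;
      vec u = solve(trimatl(cF.t()), innov);
      double k = static_cast<double>(o.n_elem);
      ll -= 0.5 * (k * log2pi + 2.0 * accu(log(cF.diag())) + dot(u, u));
      mat Finv = inv_sympd(F);
      mat K = PZ * Finv;                        // m x k
      xpt = xpt + K * innov;                    // becomes xf
      Vpt = (Vprev + Im) - K * PZ.t();
      Vpt = 0.5 * (Vpt + Vpt.t());
      xp.col(t) = xprev;  // note: xp holds the prediction mean
      Vp.slice(t) = Vprev + Im;
      xf.col(t) = xpt;
      Vf.slice(t) = Vpt;
      xprev = xpt;
      Vprev = Vpt;
    } else {
      xp.col(t) = xpt;
      Vp.slice(t) = Vpt;
      xf.col(t) = xpt;
      Vf.slice(t) = Vpt;
      xprev = xpt;
      Vprev = Vpt;
    }
  }

  if (!ok) {
    return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                              Rcpp::Named("ok") = false);
  }
  if (!smooth) {
    return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                              Rcpp::Named("ok") = true);
  }

  mat xs = xf;
  cube Vs = Vf;
  cube Cs(m, m, T, fill::zeros);  // slice t: Cov(x_{t-1}, x_t | Y)
  for (uword t = T - 1; t-- > 0;) {
    mat J = Vf.slice(t) * inv_sympd(Vp.slice(t + 1));
    xs.col(t) = xf.col(t) + J * (xs.col(t + 1) - xp.col(t + 1));
    mat V = Vf.slice(t) + J * (Vs.slice(t + 1) - Vp.slice(t + 1)) * J.t();
    Vs.slice(t) = 0.5 * (V + V.t());
    Cs.slice(t + 1) = J * Vs.slice(t + 1);
  }

  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll, Rcpp::Named("ok") = true,
      Rcpp::Named("xs") = xs, Rcpp::Named("Vs") = Vs,
      Rcpp::Named("Cs") = Cs, Rcpp::Named("xf") = xf,
      Rcpp::Named("Vf") = Vf);
}
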