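// Conditional-maximization steps of the DFA EM algorithm.
//
// dfa_mstep_obs: generalized-least-squares update of the free entries
// of (Z, a, D) given R and the smoothed state moments, accumulated by
// missingness pattern (the expected normal equations are Kronecker
// products of state moments with the embedded R^{-1}).
//
// dfa_rstats: expected residual sufficient statistics for the R
// update: per-river sums for the diagonal structures and per-time
// trace/total sums for the shared variance-covariance structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".dfa_mstep_obs_cpp")]]
Rcpp::List dfa_mstep_obs(const arma::mat& y0, const arma::mat& xs,
                         const arma::cube& Vs, const arma::mat& Rm,
                         const Rcpp::List& groups, const arma::mat& d,
                         bool has_d, bool est_a, const arma::uvec& fz) {
  const uword S = y0.n_rows, m = xs.n_rows;
  const uword p = has_d ? d.n_cols : 0;
  const uword nfz = fz.n_elem;
  const uword n_beta = nfz + (est_a ? S : 0) + S * p;

  mat G(n_beta, n_beta, fill::zeros);
  vec g(n_beta, fill::zeros);
  const uword ia0 = nfz;                 // start of a block
  const uword iD0 = nfz + (est_a ? S : 0);

  for (R_xlen_t gi = 0; gi < groups.size(); ++gi) {
    Rcpp::List grp = groups[gi];
    uvec o = Rcpp::as<uvec>(grp["o"]);     // 0-based observed rows
    uvec ts = Rcpp::as<uvec>(grp["ts"]);   // 0-based times
    if (o.n_elem == 0) continue;

    mat E(S, S, fill::zeros);
    E.submat(o, o) = inv_sympd(Rm.submat(o, o));

    mat X = xs.cols(ts);                   // m x Tg
    mat SP = X * X.t();
    for (uword j = 0; j < ts.n_elem; ++j) SP += Vs.slice(ts(j));
    mat W = E * y0.cols(ts);               // S x Tg

    mat KZZ = kron(SP, E);
    G.submat(0, 0, nfz - 1, nfz - 1) += KZZ.submat(fz, fz);
    vec gZ = vectorise(W * X.t());
    g.subvec(0, nfz - 1) += gZ.elem(fz);

    if (est_a) {
      vec sx = sum(X, 1);
      G.submat(ia0, ia0, ia0 + S - 1, ia0 + S - 1) +=
          static_cast<double>(ts.n_elem) * E;
      mat KZa = kron(sx, E);               // (S*m) x S
      mat KZa_f = KZa.rows(fz);
      G.submat(0, ia0, nfz - 1, ia0 + S - 1) += KZa_f;
      G.submat(ia0, 0, ia0 + S - 1, nfz - 1) += KZa_f.t();
      g.subvec(ia0, ia0 + S - 1) += sum(W, 1);
    }
    if (p > 0) {
      mat dg = d.rows(ts);                 // Tg x p
      mat Sxd = X * dg;                    // m x p
      mat Sdd = dg.t() * dg;               // p x p
      mat KZD = kron(Sxd, E);              // (S*m) x (S*p)
      mat KZD_f = KZD.rows(fz);
      G.submat(0, iD0, nfz - 1, iD0 + S * p - 1) += KZD_f;
      G.submat(iD0, 0, iD0 + S * p - 1, nfz - 1) += KZD_f.t();
      G.submat(iD0, iD0, iD0 + S * p - 1, iD0 + S * p - 1) += kron(Sdd, E);
      g.subvec(iD0, iD0 + S * p - 1) += vectorise(W * dg);
      if (est_a) {
        rowvec sd_ = sum(dg, 0);
        mat KaD = kron(sd_, E);            // S x (S*p)
        G.submat(ia0, iD0, ia0 + S - 1, iD0 + S * p - 1) += KaD;
        G.submat(iD0, ia0, iD0 + S * p - 1, ia0 + S - 1) += KaD.t();
      }
    }
  }

  vec beta;
  if (!solve(beta, G, g, solve_opts::likely_sympd + solve_opts::no_approx)) {
    // singular normal equations (e.g. a degenerate covariate): ridge
    double ridge = 1e-10 * trace(G) / n_beta + 1e-300;
    solve(beta, G + ridge * eye(n_beta, n_beta), g,
          solve_opts::likely_sympd + solve_opts::no_approx);
  }
  return Rcpp::List::create(Rcpp::Named("beta") = beta);
}

// [[Rcpp::export(name = ".dfa_rstats_cpp")]]
Rcpp::List dfa_rstats(const arma::mat& y, const arma::mat& mu,
                      const arma::mat& Z, const arma::cube& Vs) {
  const uword S = y.n_rows, T = y.n_cols;
  vec row_rss(S, fill::zeros);
  vec row_n(S, fill::zeros);
  vec trE(T, fill::zeros), sumE(T, fill::zeros);
  vec kk(T, fill::zeros);

  for (uword t = 0; t < T; ++t) {
    uvec o = find_finite(y.col(t));
    if (o.n_elem == 0) continue;
    mat Zo = Z.rows(o);
    vec r = y.col(t);
    vec mt = mu.col(t);
    r = r.elem(o) - mt.elem(o);
    mat ZV = Zo * Vs.slice(t);             // k x m
    vec zvz = sum(ZV % Zo, 1);             // diag(Zo Vs Zo')
    for (uword j = 0; j < o.n_elem; ++j) {
      row_rss(o(j)) += r(j) * r(j) + zvz(j);
      row_n(o(j)) += 1.0;
    }
    vec zc = sum(Zo, 0).t();               // column sums of Zo
    trE(t) = dot(r, r) + accu(zvz);
    double sr = accu(r);
    sumE(t) = sr * sr + as_scalar(zc.t() * Vs.slice(t) * zc);
    kk(t) = static_cast<double>(o.n_elem);
  }
  return Rcpp::List::create(
      Rcpp::Named("row_rss") = row_rss, Rcpp::Named("row_n") = row_n,
      Rcpp::Named("trE") = trE, Rcpp::Named("sumE") = sumE,
      Rcpp::Named("kk") = kk);
}
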