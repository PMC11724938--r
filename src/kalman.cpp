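// Linear Gaussian state-space recursions (Kalman filter, fixed-interval
// smoother, prediction-error-decomposition likelihood).
//
// Covariate effects are folded in on the R side: CB holds alpha + B x_t per
// row, CA holds tau + A x_t per row, so the recursions here only see the
// reduced system  eta_t = cb_t + F eta_{t-1} + zeta_t,
//                 y_t   = ca_t + Lam eta_t + eps_t.
// The initial state (a1, P1) is the distribution of eta at the FIRST
// occasion: no transition is applied before the first measurement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Per-person filter/smoother with row-wise missing-data handling.
// Y: T_total x p with NA marking missing entries. mode: 0 loglik only,
// 1 filtered paths, 2 smoothed paths (filtered also computed internally).
// [[Rcpp::export(name = ".kf_core")]]
Rcpp::List kf_core(const arma::mat& Y, const arma::mat& CA,
                   const arma::mat& CB, const arma::ivec& pstart,
                   const arma::ivec& plen, const arma::mat& F,
                   const arma::mat& Q, const arma::mat& Lam,
                   const arma::mat& R, const arma::vec& a1,
                   const arma::mat& P1, const int mode) {
  const uword q = F.n_rows;
  const uword n_total = Y.n_rows;
  const uword npers = pstart.n_elem;
  const mat Iq = eye(q, q);

  double nll = 0.0;
  vec nll_person(npers, fill::zeros);
  uword nobs_used = 0;
  bool ok = true;
  uword bad_row = 0;

  mat out_mean;
  cube out_cov;
  if (mode > 0) {
    out_mean.set_size(n_total, q);
    out_cov.set_size(q, q, n_total);
  }

  for (uword i = 0; i < npers && ok; ++i) {
    const uword s = (uword)pstart(i);
    const uword Ti = (uword)plen(i);

    mat af(q, Ti), ap(q, Ti);
    cube Pf(q, q, Ti), Pp(q, q, Ti);

    vec a_prev;
    mat P_prev;
    for (uword t = 0; t < Ti; ++t) {
      vec a_pred;
      mat P_pred;
      if (t == 0) {
        a_pred = a1;
        P_pred = P1;
      } else {
        a_pred = CB.row(s + t).t() + F * a_prev;
        P_pred = F * P_prev * F.t() + Q;
      }
      P_pred = 0.5 * (P_pred + P_pred.t());
      ap.col(t) = a_pred;
      Pp.slice(t) = P_pred;

      const rowvec yrow = Y.row(s + t);
      uvec obs = find_finite(yrow.t());
      if (obs.n_elem == 0) {
        af.col(t) = a_pred;
        Pf.slice(t) = P_pred;
      } else {
        const mat Lo = Lam.rows(obs);
        const vec ca_t = CA.row(s + t).t();
        const vec yv = yrow.t();
        const vec yo = yv.elem(obs) - ca_t.elem(obs);
        const vec v = yo - Lo * a_pred;
        mat S = Lo * P_pred * Lo.t() + R.submat(obs, obs);
        S = 0.5 * (S + S.t());
        mat U;
        if (!chol(U, S)) { ok = false; bad_row = s + t; break; }
        const vec z = solve(trimatl(U.t()), v);
        const double logdet = 2.0 * sum(log(U.diag()));
        const double contrib =
            0.5 * (obs.n_elem * LOG2PI + logdet + dot(z, z));
        nll += contrib;
        nll_person(i) += contrib;
        nobs_used += 1;
        const mat K = P_pred * Lo.t() * solve(trimatu(U),
                          solve(trimatl(U.t()), eye(obs.n_elem, obs.n_elem)));
        af.col(t) = a_pred + K * v;
        mat Pf_t = (Iq - K * Lo) * P_pred;
        Pf.slice(t) = 0.5 * (Pf_t + Pf_t.t());
      }
      a_prev = af.col(t);
      P_prev = Pf.slice(t);
    }
    if (!ok) break;

    if (mode == 1) {
      for (uword t = 0; t < Ti; ++t) {
        out_mean.row(s + t) = af.col(t).t();
        out_cov.slice(s + t) = Pf.slice(t);
      }
    } else if (mode == 2) {
      // Rauch-Tung-Striebel backward pass.
      vec a_sm = af.col(Ti - 1);
      mat P_sm = Pf.slice(Ti - 1);
      out_mean.row(s + Ti - 1) = a_sm.t();
      out_cov.slice(s + Ti - 1) = P_sm;
      for (uword t = Ti - 1; t-- > 0;) {
        const mat Ppn = Pp.slice(t + 1);
        mat J;
        if (!solve(J, Ppn.t(), F * Pf.slice(t).t())) {
          ok = false; bad_row = s + t; break;
        }
        J = J.t();  // J = Pf_t F' Ppn^{-1}
        a_sm = af.col(t) + J * (a_sm - ap.col(t + 1));
        mat Ps = Pf.slice(t) + J * (P_sm - Ppn) * J.t();
        P_sm = 0.5 * (Ps + Ps.t());
        out_mean.row(s + t) = a_sm.t();
        out_cov.slice(s + t) = P_sm;
      }
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("nll") = ok ? nll : R_PosInf,
      Rcpp::Named("nll_person") = nll_person,
      Rcpp::Named("nobs_used") = (int)nobs_used,
      Rcpp::Named("ok") = ok,
      Rcpp::Named("bad_row") = (int)bad_row + 1,
      Rcpp::Named("mean") = out_mean,
      Rcpp::Named("cov") = out_cov);
}

// Fast likelihood for fully observed balanced panels: the covariance
// recursion is shared across persons (it does not depend on the data), so
// the mean recursion runs for all persons at once.
// Yadj: cube(p, N, T) holding y - (tau + A x); CB: cube(q, N, T).
// [[Rcpp::export(name = ".kf_loglik_complete")]]
Rcpp::List kf_loglik_complete(const arma::cube& Yadj, const arma::cube& CB,
                              const arma::mat& F, const arma::mat& Q,
                              const arma::mat& Lam, const arma::mat& R,
                              const arma::vec& a1, const arma::mat& P1) {
  const uword p = Yadj.n_rows;
  const uword N = Yadj.n_cols;
  const uword T = Yadj.n_slices;
  const uword q = F.n_rows;
  const mat Iq = eye(q, q);

  vec nll_person(N, fill::zeros);
  bool ok = true;

  mat A_filt(q, N);
  mat P_filt(q, q);
  for (uword t = 0; t < T && ok; ++t) {
    mat A_pred;
    mat P_pred;
    if (t == 0) {
      A_pred = repmat(a1, 1, N);
      P_pred = P1;
    } else {
      A_pred = CB.slice(t) + F * A_filt;
      P_pred = F * P_filt * F.t() + Q;
    }
    P_pred = 0.5 * (P_pred + P_pred.t());

    const mat V = Yadj.slice(t) - Lam * A_pred;  // p x N innovations
    mat S = Lam * P_pred * Lam.t() + R;
    S = 0.5 * (S + S.t());
    mat U;
    if (!chol(U, S)) { ok = false; break; }
    const double logdet = 2.0 * sum(log(U.diag()));
    const mat Z = solve(trimatl(U.t()), V);       // p x N
    nll_person += 0.5 * (p * LOG2PI + logdet +
                         sum(Z % Z, 0).t());
    const mat Sinv = solve(trimatu(U),
                           solve(trimatl(U.t()), eye(p, p)));
    const mat K = P_pred * Lam.t() * Sinv;
    A_filt = A_pred + K * V;
    mat Pf = (Iq - K * Lam) * P_pred;
    P_filt = 0.5 * (Pf + Pf.t());
  }

  return Rcpp::List::create(
      Rcpp::Named("nll") = ok ? accu(nll_person) : R_PosInf,
      Rcpp::Named("nll_person") = nll_person,
      Rcpp::Named("nobs_used") = (int)(ok ? N * T : 0),
      Rcpp::Named("ok") = ok);
}
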