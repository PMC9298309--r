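// Conjugate blocked Gibbs samplers for the community stock-recruitment model
// and the Steelhead life-cycle submodel. Both models are conditionally
// linear-Gaussian. To avoid the slow mixing of naive state/coefficient
// alternation (slow-trend covariates are nearly collinear with the random-walk
// intercepts), regression coefficients are drawn from their STATE-MARGINALIZED
// Gaussian conditionals via an augmented Kalman filter (the filter is linear
// in the observations, so innovations of the regressors are filtered alongside
// the data and the GLS precision accumulated from them); latent paths are then
// drawn exactly by forward-filter backward-sampling (FFBS), and covariances by
// inverse-Wishart / inverse-gamma conjugate updates. All randomness comes from
// R's RNG, so runs are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat chol_lower_safe(const arma::mat& S) {
  arma::mat L;
  arma::mat A = arma::symmatu(S);
  double jitter = 0.0;
  for (int k = 0; k < 6; ++k) {
    if (arma::chol(L, A + jitter * arma::eye(A.n_rows, A.n_cols), "lower"))
      return L;
    jitter = (jitter == 0.0) ? 1e-10 : jitter * 100;
  }
  Rcpp::stop("covariance matrix is not positive definite");
  return L;
}

static arma::vec mvn_draw(const arma::vec& mu, const arma::mat& Sigma) {
  arma::mat L = chol_lower_safe(Sigma);
  arma::vec z(mu.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + L * z;
}

// draw from N(A^{-1} b, A^{-1}) given the precision A
static arma::vec mvn_draw_prec(const arma::mat& A, const arma::vec& b) {
  arma::mat R;
  arma::mat As = arma::symmatu(A);
  if (!arma::chol(R, As))
    Rcpp::stop("precision matrix is not positive definite");
  arma::vec mu = arma::solve(As, b);
  arma::vec z(b.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

// inverse-Wishart draw with degrees of freedom df and scale matrix S
static arma::mat rinvwish(double df, const arma::mat& S) {
  int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = chol_lower_safe(Sinv);
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat W = L * A;
  W = W * W.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// N(mu, sd^2) truncated to [0, inf)
static double rtnorm_pos(double mu, double sd) {
  double plo = R::pnorm(0.0, mu, sd, 1, 0);
  if (plo > 1.0 - 1e-12) plo = 1.0 - 1e-12;
  double u = plo + unif_rand() * (1.0 - plo);
  double x = R::qnorm(u, mu, sd, 1, 0);
  if (!std::isfinite(x) || x < 0.0) x = 1e-8;
  return x;
}

static double mvn_logpdf(const arma::vec& x, const arma::vec& mu,
                         const arma::mat& Sigma) {
  arma::mat L = chol_lower_safe(Sigma);
  arma::vec z = arma::solve(arma::trimatl(L), x - mu);
  double ldet = 2.0 * arma::sum(arma::log(L.diag()));
  return -0.5 * (x.n_elem * std::log(2.0 * M_PI) + ldet + arma::dot(z, z));
}

// ---------------------------------------------------------------------------
// generic linear-Gaussian machinery
//   obs:   y_t = Z_t s_t + B_t theta + v_t,  v_t ~ N(0, R_t)
//   state: s_t = s_{t-1} + u_t, u ~ N(0, Q), s_1 ~ N(m0, P0)
// ---------------------------------------------------------------------------

// Augmented Kalman filter: accumulates the Gaussian full conditional of theta
// with the states integrated out. The filter is linear in its observation
// input, so innovations of y and of each regressor column are propagated with
// shared gains; A += E' F^{-1} E and b += E' F^{-1} e_y per step. Also
// returns the marginal log-likelihood at theta = 0 plus the log|F| terms
// (used for slice sampling of nonlinear scalars).
static double marginal_theta_precision(const std::vector<arma::mat>& Z,
                                       const std::vector<arma::vec>& y,
                                       const std::vector<arma::mat>& B,
                                       const std::vector<arma::mat>& R,
                                       const arma::mat& Q,
                                       const arma::vec& m0, const arma::mat& P0,
                                       const arma::vec& theta0,
                                       arma::mat& A, arma::vec& b) {
  int T = y.size();
  int ds = m0.n_elem;
  int p = A.n_rows;
  arma::mat M(ds, p + 1, arma::fill::zeros);
  M.col(0) = m0;
  arma::mat P = P0;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) P += Q;
    int nob = y[t].n_elem;
    if (nob > 0) {
      // innovations for the data column and each regressor column
      arma::mat O(nob, p + 1);
      O.col(0) = y[t];
      if (p > 0) O.cols(1, p) = B[t];
      arma::mat E = O - Z[t] * M;
      arma::mat F = arma::symmatu(Z[t] * P * Z[t].t() + R[t]);
      arma::mat Fi = arma::inv_sympd(F);
      arma::vec e0 = E.col(0) - (p > 0 ? arma::vec(E.cols(1, p) * theta0)
                                       : arma::vec(nob, arma::fill::zeros));
      if (p > 0) {
        arma::mat Er = E.cols(1, p);
        arma::mat FiE = Fi * Er;
        A += Er.t() * FiE;
        b += FiE.t() * E.col(0);
      }
      double sign, ld;
      arma::log_det(ld, sign, F);
      ll += -0.5 * (nob * std::log(2.0 * M_PI) + ld +
                    arma::dot(e0, Fi * e0));
      arma::mat K = P * Z[t].t() * Fi;
      M += K * E;
      P = arma::symmatu(P - K * Z[t] * P);
    }
  }
  return ll;
}

// FFBS draw of the state path given theta (observation offsets pre-subtracted)
static arma::mat ffbs(const std::vector<arma::mat>& Z,
                      const std::vector<arma::vec>& y,
                      const std::vector<arma::mat>& R,
                      const arma::mat& Q,
                      const arma::vec& m0, const arma::mat& P0) {
  int T = y.size();
  int ds = m0.n_elem;
  arma::mat mf(ds, T);
  arma::cube Pf(ds, ds, T);
  arma::vec mpre = m0;
  arma::mat Ppre = P0;
  for (int t = 0; t < T; ++t) {
    if (t > 0) { mpre = mf.col(t - 1); Ppre = Pf.slice(t - 1) + Q; }
    if (y[t].n_elem > 0) {
      arma::mat F = arma::symmatu(Z[t] * Ppre * Z[t].t() + R[t]);
      arma::mat K = arma::solve(F, Z[t] * Ppre).t();
      mf.col(t) = mpre + K * (y[t] - Z[t] * mpre);
      Pf.slice(t) = arma::symmatu(Ppre - K * Z[t] * Ppre);
    } else {
      mf.col(t) = mpre;
      Pf.slice(t) = Ppre;
    }
  }
  arma::mat s(ds, T);
  s.col(T - 1) = mvn_draw(mf.col(T - 1), Pf.slice(T - 1));
  for (int t = T - 2; t >= 0; --t) {
    arma::mat Ppred = Pf.slice(t) + Q;
    arma::mat J = arma::solve(arma::symmatu(Ppred), Pf.slice(t)).t();
    arma::vec mu = mf.col(t) + J * (s.col(t + 1) - mf.col(t));
    arma::mat V = arma::symmatu(Pf.slice(t) - J * Ppred * J.t());
    s.col(t) = mvn_draw(mu, V);
  }
  return s;
}

// ---------------------------------------------------------------------------
// community model
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List gibbs_community_cpp(const arma::mat& Y0, const arma::umat& OBS,
                         const arma::mat& Ss, const List& Xlist,
                         bool alpha_tv, bool beta_tv,
                         int n_iter, int n_warmup, int thin,
                         const List& prior) {
  const int T = Y0.n_rows, d = Y0.n_cols;
  const double a0_sd = as<double>(prior["a0_sd"]);
  const double beta_sd = as<double>(prior["beta_sd"]);
  const double delta_sd = as<double>(prior["delta_sd"]);
  const double nu0 = as<double>(prior["nu0"]);
  const double SO_scale = as<double>(prior["SO_scale"]);
  const double SP_scale = as<double>(prior["SP_scale"]);
  const int sweeps = as<int>(prior["sweeps"]);

  std::vector<arma::mat> X(d);
  int K = 0;
  for (int j = 0; j < d; ++j) {
    X[j] = as<arma::mat>(Xlist[j]);
    if ((int)X[j].n_rows != T) stop("design matrix row mismatch");
    K += X[j].n_cols;
  }
  const int na = alpha_tv ? 0 : d;
  const int nb = beta_tv ? 0 : d;
  const int p = na + nb + K;
  const int ds = (alpha_tv ? d : 0) + (beta_tv ? d : 0);

  std::vector<arma::mat> B(T), Zs(T);
  for (int t = 0; t < T; ++t) {
    arma::mat Bt(d, p, arma::fill::zeros);
    int col = 0;
    if (!alpha_tv) for (int j = 0; j < d; ++j) Bt(j, col + j) = 1.0;
    col += na;
    if (!beta_tv) for (int j = 0; j < d; ++j) Bt(j, col + j) = -Ss(t, j);
    col += nb;
    for (int j = 0; j < d; ++j) {
      for (arma::uword k = 0; k < X[j].n_cols; ++k) Bt(j, col + k) = X[j](t, k);
      col += X[j].n_cols;
    }
    B[t] = Bt;
    arma::mat Zt(d, std::max(ds, 1), arma::fill::zeros);
    int sc = 0;
    if (alpha_tv) { for (int j = 0; j < d; ++j) Zt(j, sc + j) = 1.0; sc += d; }
    if (beta_tv) { for (int j = 0; j < d; ++j) Zt(j, sc + j) = -Ss(t, j); }
    Zs[t] = Zt;
  }
  arma::vec prior_prec(p);
  {
    int col = 0;
    for (int j = 0; j < na; ++j) prior_prec(col++) = 1.0 / (a0_sd * a0_sd);
    for (int j = 0; j < nb; ++j) prior_prec(col++) = 1.0 / (beta_sd * beta_sd);
    for (int j = col; j < p; ++j) prior_prec(j) = 1.0 / (delta_sd * delta_sd);
  }

  arma::vec theta(p, arma::fill::zeros);
  for (int j = 0; j < nb; ++j) theta(na + j) = 0.5;
  arma::mat S_O = 0.25 * arma::eye(d, d);
  arma::mat Q = 0.05 * arma::eye(std::max(ds, 1), std::max(ds, 1));
  arma::mat states(std::max(ds, 1), T, arma::fill::zeros);
  if (alpha_tv) {
    for (int j = 0; j < d; ++j) {
      double m = 0.0; int n = 0;
      for (int t = 0; t < T; ++t) if (OBS(t, j)) { m += Y0(t, j); ++n; }
      if (n > 0) states.row(j).fill(m / n);
    }
  }
  arma::mat Y = Y0;
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < d; ++j) if (!OBS(t, j)) Y(t, j) = 0.0;

  arma::vec m0v(std::max(ds, 1), arma::fill::zeros);
  arma::mat P0 = a0_sd * a0_sd *
    arma::eye(std::max(ds, 1), std::max(ds, 1));

  const int n_keep = (n_iter - n_warmup) / thin;
  arma::mat keep_theta(n_keep, p);
  arma::cube keep_states(ds > 0 ? n_keep : 0, T, ds);
  arma::cube keep_SO(d, d, n_keep);
  arma::cube keep_SP(ds > 0 ? ds : 0, ds > 0 ? ds : 0, ds > 0 ? n_keep : 0);
  arma::mat keep_ll(n_keep, T);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // 1. impute missing observations from their conditional normal
    for (int t = 0; t < T; ++t) {
      arma::uvec mis, obs;
      for (int j = 0; j < d; ++j)
        (OBS(t, j) ? obs : mis)
          .insert_rows((OBS(t, j) ? obs.n_elem : mis.n_elem),
                       arma::uvec{(arma::uword)j});
      if (mis.n_elem == 0) continue;
      arma::vec mu_t = B[t] * theta;
      if (ds > 0) mu_t += Zs[t] * states.col(0 + t);
      if (obs.n_elem == 0) {
        arma::vec draw = mvn_draw(mu_t, S_O);
        for (arma::uword i = 0; i < mis.n_elem; ++i) Y(t, mis(i)) = draw(mis(i));
      } else {
        arma::mat Soo = S_O.submat(obs, obs);
        arma::mat Smo = S_O.submat(mis, obs);
        arma::vec yo = Y.row(t).t();
        arma::vec resid = yo.elem(obs) - mu_t.elem(obs);
        arma::mat W = arma::solve(arma::symmatu(Soo), Smo.t()).t();
        arma::vec cmu = mu_t.elem(mis) + W * resid;
        arma::mat cS = arma::symmatu(S_O.submat(mis, mis) - W * Smo.t());
        arma::vec draw = mvn_draw(cmu, cS);
        for (arma::uword i = 0; i < mis.n_elem; ++i) Y(t, mis(i)) = draw(i);
      }
    }
    // 2. regression block from its state-marginalized Gaussian conditional
    {
      arma::mat A(p, p, arma::fill::zeros);
      arma::vec b(p, arma::fill::zeros);
      if (ds > 0) {
        std::vector<arma::vec> yv(T);
        std::vector<arma::mat> Rv(T);
        for (int t = 0; t < T; ++t) { yv[t] = Y.row(t).t(); Rv[t] = S_O; }
        marginal_theta_precision(Zs, yv, B, Rv, Q, m0v, P0,
                                 arma::vec(p, arma::fill::zeros), A, b);
      } else {
        arma::mat Om = arma::inv_sympd(arma::symmatu(S_O));
        for (int t = 0; t < T; ++t) {
          arma::mat OB = Om * B[t];
          A += B[t].t() * OB;
          b += OB.t() * Y.row(t).t();
        }
      }
      A.diag() += prior_prec;
      bool ok = false;
      for (int tries = 0; tries < 100 && !ok; ++tries) {
        arma::vec cand = mvn_draw_prec(A, b);
        ok = true;
        for (int j = na; j < na + nb; ++j) if (cand(j) < 0) { ok = false; break; }
        if (ok) theta = cand;
      }
      if (!ok) {
        // fallback: truncated coordinate-Gibbs on the same Gaussian
        for (int sw = 0; sw < std::max(sweeps, 3); ++sw)
          for (int j = 0; j < p; ++j) {
            double prec = A(j, j);
            double mj = (b(j) - arma::dot(A.row(j).t(), theta) +
                         A(j, j) * theta(j)) / prec;
            double sdj = std::sqrt(1.0 / prec);
            bool trunc = (j >= na && j < na + nb);
            theta(j) = trunc ? rtnorm_pos(mj, sdj) : (mj + sdj * norm_rand());
          }
      }
    }
    // 3. latent paths by FFBS given theta
    if (ds > 0) {
      std::vector<arma::vec> ystar(T);
      std::vector<arma::mat> Rv(T);
      for (int t = 0; t < T; ++t) {
        ystar[t] = Y.row(t).t() - B[t] * theta;
        Rv[t] = S_O;
      }
      states = ffbs(Zs, ystar, Rv, Q, m0v, P0);
    }
    // 4. observation covariance
    {
      arma::mat SSm = SO_scale * arma::eye(d, d);
      for (int t = 0; t < T; ++t) {
        arma::vec v = Y.row(t).t() - B[t] * theta;
        if (ds > 0) v -= Zs[t] * states.col(t);
        SSm += v * v.t();
      }
      S_O = rinvwish(nu0 + T, SSm);
    }
    // 5. process covariance (block per time-varying component)
    if (ds > 0) {
      arma::mat Qn(ds, ds, arma::fill::zeros);
      int nblk = (alpha_tv ? 1 : 0) + (beta_tv ? 1 : 0);
      for (int blk = 0; blk < nblk; ++blk) {
        arma::uvec idx = arma::regspace<arma::uvec>(blk * d, blk * d + d - 1);
        arma::mat SSm = SP_scale * arma::eye(d, d);
        for (int t = 1; t < T; ++t) {
          arma::vec u = states.submat(idx, arma::uvec{(arma::uword)t}) -
                        states.submat(idx, arma::uvec{(arma::uword)(t - 1)});
          SSm += u * u.t();
        }
        Qn.submat(idx, idx) = rinvwish(nu0 + T - 1, SSm);
      }
      Q = Qn;
    }
    // store
    if (it >= n_warmup && ((it - n_warmup) % thin == 0)) {
      keep_theta.row(kept) = theta.t();
      if (ds > 0) {
        for (int c = 0; c < ds; ++c)
          for (int t = 0; t < T; ++t) keep_states(kept, t, c) = states(c, t);
        keep_SP.slice(kept) = Q;
      }
      keep_SO.slice(kept) = S_O;
      for (int t = 0; t < T; ++t) {
        arma::uvec obs;
        for (int j = 0; j < d; ++j)
          if (OBS(t, j)) obs.insert_rows(obs.n_elem, arma::uvec{(arma::uword)j});
        if (obs.n_elem == 0) { keep_ll(kept, t) = 0.0; continue; }
        arma::vec mu = B[t] * theta;
        if (ds > 0) mu += Zs[t] * states.col(t);
        arma::vec yo = Y0.row(t).t();
        keep_ll(kept, t) = mvn_logpdf(yo.elem(obs), mu.elem(obs),
                                      S_O.submat(obs, obs));
      }
      ++kept;
    }
  }
  return List::create(_["theta"] = keep_theta, _["states"] = keep_states,
                      _["Sigma_O"] = keep_SO, _["Sigma_P"] = keep_SP,
                      _["loglik"] = keep_ll);
}

// ---------------------------------------------------------------------------
// Steelhead life-cycle model
// ---------------------------------------------------------------------------

struct ShData {
  arma::vec l, Sa, Tt, F, lnS;
  arma::mat Xm, Xt;
  arma::uvec ol, oS, oT;
  int T, km, kt;
};

// observation system at the current coefficient values; theta_lin is
// (delta_m, delta_S2, delta_TS, delta_T) and dS1 enters the state loading
static void sh_system(const ShData& D, double dS1,
                      std::vector<arma::mat>& Z, std::vector<arma::vec>& y,
                      std::vector<arma::mat>& Bm, std::vector<arma::mat>& R,
                      const arma::vec& sig2) {
  int p = D.km + 2 + D.kt;
  for (int t = 0; t < D.T; ++t) {
    int nob = D.ol(t) + D.oS(t) + D.oT(t);
    arma::mat Zt(nob, 3, arma::fill::zeros);
    arma::vec yt(nob), rt(nob);
    arma::mat Bt(nob, p, arma::fill::zeros);
    int r = 0;
    if (D.ol(t)) {
      Zt(r, 0) = 1.0; yt(r) = D.l(t); rt(r) = sig2(0);
      for (int k = 0; k < D.km; ++k) Bt(r, k) = D.Xm(t, k);
      ++r;
    }
    if (D.oS(t)) {
      Zt(r, 0) = dS1; Zt(r, 1) = 1.0;
      yt(r) = D.Sa(t); rt(r) = sig2(1);
      for (int k = 0; k < D.km; ++k) Bt(r, k) = dS1 * D.Xm(t, k);
      Bt(r, D.km) = D.F(t);
      ++r;
    }
    if (D.oT(t)) {
      Zt(r, 2) = 1.0; yt(r) = D.Tt(t); rt(r) = sig2(2);
      Bt(r, D.km + 1) = D.lnS(t);
      for (int k = 0; k < D.kt; ++k) Bt(r, D.km + 2 + k) = D.Xt(t, k);
      ++r;
    }
    Z[t] = Zt; y[t] = yt; Bm[t] = Bt; R[t] = arma::diagmat(rt);
  }
}

// marginal log-likelihood (states integrated out) at given coefficients
static double sh_marginal_ll(const ShData& D, double dS1,
                             const arma::vec& theta_lin,
                             const arma::vec& sig2, const arma::vec& q2,
                             const arma::vec& m0, const arma::mat& P0) {
  int p = D.km + 2 + D.kt;
  std::vector<arma::mat> Z(D.T), Bm(D.T), R(D.T);
  std::vector<arma::vec> y(D.T);
  sh_system(D, dS1, Z, y, Bm, R, sig2);
  arma::mat A(p, p, arma::fill::zeros);
  arma::vec b(p, arma::fill::zeros);
  arma::mat Q = arma::diagmat(q2);
  return marginal_theta_precision(Z, y, Bm, R, Q, m0, P0, theta_lin, A, b);
}

// [[Rcpp::export]]
List gibbs_steelhead_cpp(const arma::vec& l, const arma::vec& Sa,
                         const arma::vec& Tt, const arma::vec& F,
                         const arma::vec& lnS,
                         const arma::mat& Xm, const arma::mat& Xt,
                         int n_iter, int n_warmup, int thin,
                         const List& prior) {
  ShData D;
  D.l = l; D.Sa = Sa; D.Tt = Tt; D.F = F; D.lnS = lnS; D.Xm = Xm; D.Xt = Xt;
  D.T = l.n_elem; D.km = Xm.n_cols; D.kt = Xt.n_cols;
  D.ol.set_size(D.T); D.oS.set_size(D.T); D.oT.set_size(D.T);
  for (int t = 0; t < D.T; ++t) {
    D.ol(t) = std::isfinite(l(t)) ? 1 : 0;
    D.oS(t) = std::isfinite(Sa(t)) ? 1 : 0;
    D.oT(t) = (std::isfinite(Tt(t)) && std::isfinite(lnS(t))) ? 1 : 0;
  }
  const int nl = arma::accu(D.ol), nS = arma::accu(D.oS), nT = arma::accu(D.oT);
  if (nl < 3 || nS < 3 || nT < 3) stop("too few observed years in a series");
  const double delta_sd = as<double>(prior["delta_sd"]);
  const arma::vec init_sd = as<arma::vec>(prior["init_sd"]);
  const double a_obs = as<double>(prior["a_obs"]), b_obs = as<double>(prior["b_obs"]);
  const double a_rw = as<double>(prior["a_rw"]), b_rw = as<double>(prior["b_rw"]);

  const int p = D.km + 2 + D.kt;   // delta_m, delta_S2, delta_TS, delta_T
  arma::vec theta_lin(p, arma::fill::zeros);
  double dS1 = 0.0;
  arma::vec sig2 = {0.5, 0.5, 25.0};
  arma::vec q2 = {0.05, 0.05, 4.0};
  arma::mat states(3, D.T, arma::fill::zeros);
  states.row(0).fill(arma::mean(D.l.elem(arma::find(D.ol))));
  states.row(1).fill(arma::mean(D.Sa.elem(arma::find(D.oS))));
  states.row(2).fill(arma::mean(D.Tt.elem(arma::find(D.oT))));
  arma::vec m0 = {states(0, 0), states(1, 0), states(2, 0)};
  arma::mat P0 = arma::diagmat(arma::square(init_sd));

  const int n_keep = (n_iter - n_warmup) / thin;
  arma::mat keep_dm(n_keep, D.km), keep_dT(n_keep, D.kt);
  arma::mat keep_sc(n_keep, 3);
  arma::mat keep_sig(n_keep, 6);
  arma::cube keep_states(n_keep, D.T, 3);
  arma::vec keep_neg(n_keep);
  arma::mat keep_ll(n_keep, D.T);

  auto rinvgamma = [](double a, double b) {
    return 2.0 * b / R::rchisq(2.0 * a);
  };

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // 1. linear coefficients from their state-marginalized conditional
    {
      std::vector<arma::mat> Z(D.T), Bm(D.T), R(D.T);
      std::vector<arma::vec> y(D.T);
      sh_system(D, dS1, Z, y, Bm, R, sig2);
      arma::mat A(p, p, arma::fill::zeros);
      arma::vec b(p, arma::fill::zeros);
      arma::mat Q = arma::diagmat(q2);
      marginal_theta_precision(Z, y, Bm, R, Q, m0, P0,
                               arma::vec(p, arma::fill::zeros), A, b);
      A.diag() += 1.0 / (delta_sd * delta_sd);
      theta_lin = mvn_draw_prec(A, b);
    }
    // 2. dS1 by slice sampling on its state-marginalized posterior
    {
      auto logpost = [&](double v) {
        return sh_marginal_ll(D, v, theta_lin, sig2, q2, m0, P0) +
          R::dnorm(v, 0.0, delta_sd, 1);
      };
      double x0 = dS1;
      double ly = logpost(x0) + std::log(unif_rand());
      double w = 0.5;
      double L = x0 - w * unif_rand(), Rr = L + w;
      for (int k = 0; k < 30 && logpost(L) > ly; ++k) L -= w;
      for (int k = 0; k < 30 && logpost(Rr) > ly; ++k) Rr += w;
      for (int k = 0; k < 100; ++k) {
        double x1 = L + unif_rand() * (Rr - L);
        if (logpost(x1) > ly) { dS1 = x1; break; }
        if (x1 < x0) L = x1; else Rr = x1;
      }
    }
    // 3. states by FFBS given coefficients
    {
      std::vector<arma::mat> Z(D.T), Bm(D.T), R(D.T);
      std::vector<arma::vec> y(D.T);
      sh_system(D, dS1, Z, y, Bm, R, sig2);
      std::vector<arma::vec> ystar(D.T);
      for (int t = 0; t < D.T; ++t)
        ystar[t] = y[t] - Bm[t] * theta_lin;
      arma::mat Q = arma::diagmat(q2);
      states = ffbs(Z, ystar, R, Q, m0, P0);
    }
    // 4. variances and diagnostics
    arma::vec dm = theta_lin.subvec(0, D.km - 1);
    double dS2 = theta_lin(D.km), dTS = theta_lin(D.km + 1);
    arma::vec dT = D.kt > 0 ? theta_lin.subvec(D.km + 2, p - 1) : arma::vec();
    double ssl = 0.0, ssS = 0.0, ssT = 0.0;
    int negpred = 0;
    for (int t = 0; t < D.T; ++t) {
      double mt = states(0, t) + arma::dot(dm, D.Xm.row(t).t());
      double muS = states(1, t) + dS1 * mt + dS2 * D.F(t);
      if (muS < 0) ++negpred;
      if (D.ol(t)) { double e = D.l(t) - mt; ssl += e * e; }
      if (D.oS(t)) { double e = D.Sa(t) - muS; ssS += e * e; }
      if (D.oT(t)) {
        double e = D.Tt(t) - (states(2, t) + dTS * D.lnS(t) +
                              (D.kt > 0 ? arma::dot(dT, D.Xt.row(t).t()) : 0.0));
        ssT += e * e;
      }
    }
    sig2(0) = rinvgamma(a_obs + nl / 2.0, b_obs + ssl / 2.0);
    sig2(1) = rinvgamma(a_obs + nS / 2.0, b_obs + ssS / 2.0);
    sig2(2) = rinvgamma(a_obs + nT / 2.0, b_obs + ssT / 2.0);
    double um = 0.0, uS = 0.0, uT = 0.0;
    for (int t = 1; t < D.T; ++t) {
      um += std::pow(states(0, t) - states(0, t - 1), 2);
      uS += std::pow(states(1, t) - states(1, t - 1), 2);
      uT += std::pow(states(2, t) - states(2, t - 1), 2);
    }
    q2(0) = rinvgamma(a_rw + (D.T - 1) / 2.0, b_rw + um / 2.0);
    q2(1) = rinvgamma(a_rw + (D.T - 1) / 2.0, b_rw + uS / 2.0);
    q2(2) = rinvgamma(a_rw + (D.T - 1) / 2.0, b_rw + uT / 2.0);

    if (it >= n_warmup && ((it - n_warmup) % thin == 0)) {
      keep_dm.row(kept) = dm.t();
      if (D.kt > 0) keep_dT.row(kept) = dT.t();
      keep_sc.row(kept) = arma::rowvec{dS1, dS2, dTS};
      keep_sig.row(kept) = arma::rowvec{std::sqrt(sig2(0)), std::sqrt(sig2(1)),
                                        std::sqrt(sig2(2)), std::sqrt(q2(0)),
                                        std::sqrt(q2(1)), std::sqrt(q2(2))};
      for (int t = 0; t < D.T; ++t)
        for (int c = 0; c < 3; ++c) keep_states(kept, t, c) = states(c, t);
      keep_neg(kept) = negpred;
      for (int t = 0; t < D.T; ++t) {
        double llt = 0.0;
        double mt = states(0, t) + arma::dot(dm, D.Xm.row(t).t());
        if (D.ol(t)) llt += R::dnorm(D.l(t), mt, std::sqrt(sig2(0)), 1);
        if (D.oS(t)) llt += R::dnorm(D.Sa(t),
                                     states(1, t) + dS1 * mt + dS2 * D.F(t),
                                     std::sqrt(sig2(1)), 1);
        if (D.oT(t)) llt += R::dnorm(D.Tt(t),
                                     states(2, t) + dTS * D.lnS(t) +
                                       (D.kt > 0 ? arma::dot(dT, D.Xt.row(t).t())
                                                 : 0.0),
                                     std::sqrt(sig2(2)), 1);
        keep_ll(kept, t) = llt;
      }
      ++kept;
    }
  }
  return List::create(_["delta_m"] = keep_dm, _["delta_T"] = keep_dT,
                      _["scalars"] = keep_sc, _["sigma"] = keep_sig,
                      _["states"] = keep_states, _["neg_pred"] = keep_neg,
                      _["loglik"] = keep_ll);
}
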