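// Gibbs sampler core for recursive structural equation models with
// additive genetic effects (u ~ N(0, G0 (x) A)) and diagonal residual
// covariance. Full conditionals:
//   (beta_j, lambda_j.) | .  ~ MVN (flat prior; per-trait linear model)
//   u                   | .  ~ MVN, updated in per-animal t-blocks via A^-1
//   G0                  | .  ~ IW(nuG + q, G0prior + U' A^-1 U)
//   psi_j               | .  ~ scaled-inv-chi2(nupsi + n,
//                              (nupsi s2_j + e_j'e_j) / (nupsi + n))
// Uses R's RNG so chains are reproducible through set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat rinvwishart(double df, const mat& S) {
  // G ~ IW(df, S): draw W ~ Wishart(df, S^-1) by Bartlett, return W^-1
  const uword t = S.n_rows;
  mat Sinv = inv_sympd(symmatu(S));
  mat L = chol(Sinv, "lower");
  mat A(t, t, fill::zeros);
  for (uword i = 0; i < t; ++i) {
    A(i, i) = std::sqrt(::Rf_rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = ::norm_rand();
  }
  mat LA = L * A;
  return inv_sympd(symmatu(LA * LA.t()));
}

// [[Rcpp::export]]
Rcpp::List gibbs_sem_cpp(const arma::mat& Y,          // n x t phenotypes
                         const arma::uvec& season,    // n, 0-based
                         const int n_seasons,
                         const arma::uvec& anim,      // n, 0-based pedigree row
                         const arma::ivec& row_of,    // q, phenotype row or -1
                         const arma::sp_mat& Ainv,    // q x q
                         const Rcpp::List& parents,   // per trait: 0-based trait idx
                         const arma::mat& G0_prior, const double nu_G,
                         const arma::vec& s2, const double nu_psi,
                         const arma::mat& G0_init,
                         const int n_iter, const int burnin, const int thin,
                         const Rcpp::Nullable<Rcpp::List>& init = R_NilValue) {
  Rcpp::RNGScope scope;
  const uword n = Y.n_rows, t = Y.n_cols, q = Ainv.n_rows;
  const uword p = (uword)n_seasons;

  // fixed per-trait designs W_j = [season dummies, parent phenotypes]
  std::vector<mat> W(t), WR(t);   // WR: upper chol of W'W
  std::vector<uvec> pa(t);
  uword n_free = 0;
  for (uword j = 0; j < t; ++j) {
    Rcpp::IntegerVector pj = parents[j];
    pa[j] = uvec(pj.size());
    for (int k = 0; k < pj.size(); ++k) pa[j](k) = (uword)pj[k];
    n_free += pa[j].n_elem;
    mat Wj(n, p + pa[j].n_elem, fill::zeros);
    for (uword i = 0; i < n; ++i) Wj(i, season(i)) = 1.0;
    for (uword k = 0; k < pa[j].n_elem; ++k) Wj.col(p + k) = Y.col(pa[j](k));
    W[j] = Wj;
    mat WtW = Wj.t() * Wj;
    mat R;
    if (!chol(R, WtW))
      Rcpp::stop("fixed/structural effects not estimable for trait %d", j + 1);
    WR[j] = R;
  }

  // state
  std::vector<vec> theta(t);
  vec psi = s2;
  mat U(q, t, fill::zeros);
  mat G0 = G0_init;
  mat Fit(n, t, fill::zeros);
  // start genetic effects at half the centered phenotype (a crude
  // heritability-0.5 guess): without it, the early structural
  // coefficients soak up genetic covariance and burn-in is much longer
  rowvec ybar = mean(Y, 0);
  for (uword i = 0; i < q; ++i) {
    int r0 = row_of(i);
    if (r0 >= 0) U.row(i) = 0.5 * (Y.row((uword)r0) - ybar);
  }
  for (uword j = 0; j < t; ++j) {          // OLS start on y - u0
    vec ytil0 = Y.col(j);
    for (uword i = 0; i < n; ++i) ytil0(i) -= U(anim(i), j);
    vec rhs = W[j].t() * ytil0;
    theta[j] = solve(trimatu(WR[j]), solve(trimatl(WR[j].t()), rhs));
    Fit.col(j) = W[j] * theta[j];
    vec e = ytil0 - Fit.col(j);
    psi(j) = dot(e, e) / std::max((double)n - (double)theta[j].n_elem, 1.0);
  }
  if (init.isNotNull()) {                  // warm start from a given state
    Rcpp::List st(init);
    mat Beta = Rcpp::as<mat>(st["beta"]);
    vec Lam = Rcpp::as<vec>(st["lambda"]);
    psi = Rcpp::as<vec>(st["psi"]);
    G0 = Rcpp::as<mat>(st["g0"]);
    U = Rcpp::as<mat>(st["u"]);
    uword k = 0;
    for (uword j = 0; j < t; ++j) {
      for (uword sidx = 0; sidx < p; ++sidx) theta[j](sidx) = Beta(sidx, j);
      for (uword a = 0; a < pa[j].n_elem; ++a) theta[j](p + a) = Lam(k++);
      Fit.col(j) = W[j] * theta[j];
    }
  }

  const int m = (n_iter - burnin) / thin;
  mat lam_draws(m, n_free), beta_draws(m, p * t), psi_draws(m, t),
      g0_draws(m, t * t);
  vec dev_draws(m);
  mat Umean(q, t, fill::zeros);

  mat G0inv = inv_sympd(symmatu(G0));
  int stored = 0;
  const double log2pi = std::log(2.0 * M_PI);
  // reusable buffers for the per-animal updates
  vec ucross(t), rhsbuf(t), mbuf(t);
  mat Pbuf(t, t), Lbuf(t, t, fill::zeros);

  for (int iter = 1; iter <= n_iter; ++iter) {
    // (a) per-trait location parameters (beta_j, lambda_j.) jointly
    for (uword j = 0; j < t; ++j) {
      vec ytil = Y.col(j);
      for (uword i = 0; i < n; ++i) ytil(i) -= U(anim(i), j);
      vec rhs = W[j].t() * ytil;
      vec mean = solve(trimatu(WR[j]), solve(trimatl(WR[j].t()), rhs));
      vec z(theta[j].n_elem);
      for (uword k = 0; k < z.n_elem; ++k) z(k) = ::norm_rand();
      theta[j] = mean + std::sqrt(psi(j)) * solve(trimatu(WR[j]), z);
      Fit.col(j) = W[j] * theta[j];
    }

    // (b) genetic effects, per-animal t-blocks over the whole pedigree
    vec dinv = 1.0 / psi;
    for (uword i = 0; i < q; ++i) {
      double aii = 0.0;
      ucross.zeros();
      for (sp_mat::const_col_iterator it = Ainv.begin_col(i);
           it != Ainv.end_col(i); ++it) {
        const uword k = it.row();
        if (k == i) { aii = *it; continue; }
        const double a = *it;
        for (uword j = 0; j < t; ++j) ucross(j) += a * U(k, j);
      }
      Pbuf = aii * G0inv;
      rhsbuf = -(G0inv * ucross);
      int r = row_of(i);
      if (r >= 0) {
        for (uword j = 0; j < t; ++j) {
          Pbuf(j, j) += dinv(j);
          rhsbuf(j) += dinv(j) * (Y((uword)r, j) - Fit((uword)r, j));
        }
      }
      // hand-rolled lower Cholesky P = L L' and solves (t is tiny)
      for (uword c = 0; c < t; ++c) {
        double s = Pbuf(c, c);
        for (uword k2 = 0; k2 < c; ++k2) s -= Lbuf(c, k2) * Lbuf(c, k2);
        if (s <= 0.0) Rcpp::stop("u-update precision not PD");
        Lbuf(c, c) = std::sqrt(s);
        for (uword r2 = c + 1; r2 < t; ++r2) {
          double v = Pbuf(r2, c);
          for (uword k2 = 0; k2 < c; ++k2) v -= Lbuf(r2, k2) * Lbuf(c, k2);
          Lbuf(r2, c) = v / Lbuf(c, c);
        }
      }
      // mean: solve L w = rhs, then L' m = w; draw: m += L'^{-1} z
      for (uword r2 = 0; r2 < t; ++r2) {
        double v = rhsbuf(r2);
        for (uword k2 = 0; k2 < r2; ++k2) v -= Lbuf(r2, k2) * mbuf(k2);
        mbuf(r2) = v / Lbuf(r2, r2);
      }
      for (uword j = 0; j < t; ++j) mbuf(j) += ::norm_rand();
      for (uword r3 = t; r3-- > 0; ) {
        double v = mbuf(r3);
        for (uword k2 = r3 + 1; k2 < t; ++k2) v -= Lbuf(k2, r3) * U(i, k2);
        U(i, r3) = v / Lbuf(r3, r3);
      }
    }

    // (c) genetic covariance
    mat S = G0_prior + U.t() * (Ainv * U);
    G0 = rinvwishart(nu_G + (double)q, symmatu(S));
    G0inv = inv_sympd(symmatu(G0));

    // (d) residual variances + per-draw conditional deviance
    double dev = 0.0;
    for (uword j = 0; j < t; ++j) {
      vec e = Y.col(j) - Fit.col(j);
      for (uword i = 0; i < n; ++i) e(i) -= U(anim(i), j);
      double sse = dot(e, e);
      psi(j) = (nu_psi * s2(j) + sse) / ::Rf_rchisq(nu_psi + (double)n);
      dev += (double)n * (log2pi + std::log(psi(j))) + sse / psi(j);
    }

    if (iter > burnin && (iter - burnin) % thin == 0) {
      uword k = 0;
      for (uword j = 0; j < t; ++j)
        for (uword a = 0; a < pa[j].n_elem; ++a)
          lam_draws(stored, k++) = theta[j](p + a);
      for (uword j = 0; j < t; ++j)
        for (uword sidx = 0; sidx < p; ++sidx)
          beta_draws(stored, j * p + sidx) = theta[j](sidx);
      psi_draws.row(stored) = psi.t();
      g0_draws.row(stored) = vectorise(G0).t();
      dev_draws(stored) = dev;
      Umean += U;
      ++stored;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }
  if (stored > 0) Umean /= (double)stored;

  return Rcpp::List::create(
    Rcpp::Named("lambda") = lam_draws, Rcpp::Named("beta") = beta_draws,
    Rcpp::Named("psi") = psi_draws, Rcpp::Named("g0") = g0_draws,
    Rcpp::Named("deviance") = dev_draws, Rcpp::Named("u_mean") = Umean,
    Rcpp::Named("n_stored") = stored);
}
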