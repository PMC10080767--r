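// Per-relation multi-head neighbour attention: forward and backward.
// One head: pair score S_ij = s1_i + s2_j with s1 = Z a1, s2 = Z a2 and
// Z = X W; E = LeakyReLU(S); alpha = softmax of E over the attended set
// (mask); head output = ELU(alpha Z). Dropout on alpha uses the R RNG
// stream (column-major) so runs are reproducible from set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat elu_mat(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0 ? v : std::expm1(v); });
  return y;
}

static inline mat elu_grad_mat(const mat& x) {
  mat y = x;
  y.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
  return y;
}

// [[Rcpp::export(name = ".intra_fwd")]]
Rcpp::List intra_fwd(const arma::mat& Xd, const arma::mat& W,
                     const arma::mat& a1, const arma::mat& a2,
                     const arma::umat& mask, bool training,
                     double keep, double slope, bool keepE) {
  const uword n = Xd.n_rows, K = a1.n_cols, dh = a1.n_rows;
  mat Z = Xd * W;
  mat out(n, K * dh);
  uvec off = find(mask == 0);
  uvec on = find(mask != 0);

  cube alpha(n, n, K), pre(n, dh, K), spos(n, n, K);
  cube alphad, E, dmask;
  if (training) { alphad.set_size(n, n, K); dmask.set_size(n, n, K); }
  if (keepE) E.set_size(n, n, K);

  for (uword k = 0; k < K; ++k) {
    mat Zk = Z.cols(k * dh, (k + 1) * dh - 1);
    vec s1 = Zk * a1.col(k);
    vec s2 = Zk * a2.col(k);
    mat S = repmat(s1, 1, n);
    S.each_row() += s2.t();
    mat sp = conv_to<mat>::from(S > 0);
    spos.slice(k) = sp;
    mat Ek = S % (slope + (1.0 - slope) * sp);
    if (keepE) E.slice(k) = Ek;
    Ek.elem(off).fill(-datum::inf);
    vec mx = max(Ek, 1);
    mat P = exp(Ek.each_col() - mx);
    P.elem(off).zeros();
    vec rs = sum(P, 1);
    mat al = P.each_col() / rs;
    alpha.slice(k) = al;
    const mat* use = &al;
    mat ald;
    if (training) {
      // draw only for attended entries (column-major order); off-mask
      // coefficients are zero regardless, so no RNG is spent on them
      mat dm(n, n, fill::ones);
      for (uword t = 0; t < on.n_elem; ++t)
        dm(on(t)) = R::unif_rand() < keep ? 1.0 : 0.0;
      dmask.slice(k) = dm;
      ald = (al % dm) / keep;
      alphad.slice(k) = ald;
      use = &ald;
    }
    mat prek = (*use) * Zk;
    pre.slice(k) = prek;
    out.cols(k * dh, (k + 1) * dh - 1) = elu_mat(prek);
  }
  Rcpp::List res = Rcpp::List::create(
    Rcpp::Named("x") = out, Rcpp::Named("Z") = Z,
    Rcpp::Named("alpha") = alpha, Rcpp::Named("pre") = pre,
    Rcpp::Named("spos") = spos);
  if (training) {
    res["alphad"] = alphad;
    res["dmask"] = dmask;
  }
  if (keepE) res["E"] = E;
  return res;
}

// [[Rcpp::export(name = ".intra_bwd")]]
Rcpp::List intra_bwd(const arma::mat& dxr, const arma::mat& Z,
                     const arma::mat& Xd,
                     const arma::mat& a1, const arma::mat& a2,
                     const arma::cube& alpha, const arma::cube& pre,
                     const arma::cube& spos,
                     Rcpp::Nullable<Rcpp::NumericVector> alphad_,
                     Rcpp::Nullable<Rcpp::NumericVector> dmask_,
                     double keep, double slope) {
  const uword n = Z.n_rows, K = a1.n_cols, dh = a1.n_rows;
  const bool training = alphad_.isNotNull();
  cube alphad, dmaskc;
  if (training) {
    Rcpp::NumericVector av(alphad_.get());
    alphad = cube(av.begin(), n, n, K, false);
    Rcpp::NumericVector dv(dmask_.get());
    dmaskc = cube(dv.begin(), n, n, K, false);
  }
  mat gW(Xd.n_cols, K * dh, fill::zeros);
  mat ga1(dh, K, fill::zeros), ga2(dh, K, fill::zeros);

  for (uword k = 0; k < K; ++k) {
    mat Zk = Z.cols(k * dh, (k + 1) * dh - 1);
    mat dpre = dxr.cols(k * dh, (k + 1) * dh - 1) % elu_grad_mat(pre.slice(k));
    const mat& al = alpha.slice(k);
    mat dA = dpre * Zk.t();
    mat dZk = training ? mat(alphad.slice(k).t() * dpre) : mat(al.t() * dpre);
    mat dalpha = training ? mat((dA % dmaskc.slice(k)) / keep) : dA;
    vec dot = sum(al % dalpha, 1);
    mat dE = al % (dalpha.each_col() - dot);
    mat dS = dE % (slope + (1.0 - slope) * spos.slice(k));
    vec ds1 = sum(dS, 1);
    vec ds2 = sum(dS, 0).t();
    dZk += ds1 * a1.col(k).t() + ds2 * a2.col(k).t();
    ga1.col(k) = Zk.t() * ds1;
    ga2.col(k) = Zk.t() * ds2;
    gW.cols(k * dh, (k + 1) * dh - 1) = Xd.t() * dZk;
  }
  return Rcpp::List::create(Rcpp::Named("gW") = gW,
                            Rcpp::Named("ga1") = ga1,
                            Rcpp::Named("ga2") = ga2);
}
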