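#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cumulative SIMPLS regression coefficients for a single response.
// X and y must already be centred (and usually autoscaled). Columns of B
// hold the coefficient vector for models with 1..ncomp latent variables.
// If the residual cross-product vanishes before ncomp components are
// extracted (rank exhaustion), the last informative column is carried
// forward; ncomp_eff reports the number actually extracted.
static int simpls_coefs(const mat& X, const vec& y, int ncomp, mat& B) {
  const uword p = X.n_cols;
  vec s = X.t() * y;
  mat V(p, ncomp, fill::zeros);
  mat Wn(p, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros);
  int a = 0;
  for (a = 0; a < ncomp; ++a) {
    double snorm = norm(s);
    if (snorm < 1e-12) break;
    vec w = s / snorm;            // weight with w'w = 1
    vec t = X * w;
    double tnorm = norm(t);
    if (tnorm < 1e-12) break;
    t /= tnorm;
    w /= tnorm;                   // so that scores = X * Wn are orthonormal
    vec pa = X.t() * t;
    q(a) = dot(y, t);
    vec v = pa;
    if (a > 0) {
      mat Vp = V.cols(0, a - 1);
      v -= Vp * (Vp.t() * pa);
    }
    double vnorm = norm(v);
    if (vnorm < 1e-12) break;
    v /= vnorm;
    V.col(a) = v;
    Wn.col(a) = w;
    s -= v * dot(v, s);
    B.col(a) = Wn.cols(0, a) * q.subvec(0, a);
  }
  for (int k = a; k < ncomp; ++k)
    B.col(k) = (a > 0) ? B.col(a - 1) : vec(p, fill::zeros);
  return a;
}

// Full SIMPLS decomposition (weights, loadings, scores, explained variance)
// for a single centred/scaled response.
// [[Rcpp::export]]
Rcpp::List simpls_core(const arma::mat& X, const arma::vec& y, int ncomp) {
  const uword n = X.n_rows, p = X.n_cols;
  vec s = X.t() * y;
  mat V(p, ncomp, fill::zeros), Wu(p, ncomp, fill::zeros),
      Wn(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros),
      T(n, ncomp, fill::zeros), B(p, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros), evx(ncomp, fill::zeros), evy(ncomp, fill::zeros);
  const double ssx = accu(X % X), ssy = dot(y, y);
  int a = 0;
  for (a = 0; a < ncomp; ++a) {
    double snorm = norm(s);
    if (snorm < 1e-12) break;
    vec w = s / snorm;
    Wu.col(a) = w;
    vec t = X * w;
    double tnorm = norm(t);
    if (tnorm < 1e-12) break;
    t /= tnorm;
    w /= tnorm;
    vec pa = X.t() * t;
    double qa = dot(y, t);
    vec v = pa;
    if (a > 0) {
      mat Vp = V.cols(0, a - 1);
      v -= Vp * (Vp.t() * pa);
    }
    double vnorm = norm(v);
    if (vnorm < 1e-12) break;
    v /= vnorm;
    V.col(a) = v;
    Wn.col(a) = w;
    P.col(a) = pa;
    T.col(a) = t;
    q(a) = qa;
    if (ssx > 0) evx(a) = dot(pa, pa) / ssx * 100.0;
    if (ssy > 0) evy(a) = qa * qa / ssy * 100.0;
    s -= v * dot(v, s);
    B.col(a) = Wn.cols(0, a) * q.subvec(0, a);
  }
  int eff = a;
  for (int k = eff; k < ncomp; ++k)
    B.col(k) = (eff > 0) ? B.col(eff - 1) : vec(p, fill::zeros);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = B,
      Rcpp::Named("weights") = Wu,
      Rcpp::Named("weights_scaled") = Wn,
      Rcpp::Named("x_loadings") = P,
      Rcpp::Named("y_loadings") = q,
      Rcpp::Named("scores") = T,
      Rcpp::Named("explained_x") = evx,
      Rcpp::Named("explained_y") = evy,
      Rcpp::Named("ncomp_eff") = eff);
}

// Leave-one-out cross-validation of SIMPLS over 1..lv_max latent variables.
// X and y are on their raw scale; autoscaling is re-estimated inside every
// fold so the held-out row never leaks into the scaling parameters.
// Returns the n x lv_max matrix of held-out predictions (y units).
// [[Rcpp::export]]
arma::mat loocv_predictions_core(const arma::mat& X, const arma::vec& y,
                                 int lv_max) {
  const int n = X.n_rows, p = X.n_cols;
  int A = std::min(lv_max, std::min(p, n - 2));
  if (A < 1) A = 1;
  mat pred(n, A, fill::zeros);
  mat B(p, A);
  for (int i = 0; i < n; ++i) {
    mat Xt(n - 1, p);
    vec yt(n - 1);
    int k = 0;
    for (int r = 0; r < n; ++r) {
      if (r == i) continue;
      Xt.row(k) = X.row(r);
      yt(k) = y(r);
      ++k;
    }
    rowvec mu = mean(Xt, 0);
    rowvec sd = stddev(Xt, 0, 0);
    for (int j = 0; j < p; ++j)
      if (sd(j) < 1e-10) sd(j) = 1.0;  // constant column: centred to zero
    double my = mean(yt), sy = stddev(yt);
    bool flat_y = (sy < 1e-12);
    if (flat_y) sy = 1.0;
    mat Xs = Xt.each_row() - mu;
    Xs.each_row() /= sd;
    vec ys = (yt - my) / sy;
    B.zeros();
    simpls_coefs(Xs, ys, A, B);
    rowvec xq = (X.row(i) - mu) / sd;
    for (int a2 = 0; a2 < A; ++a2) {
      double yq = flat_y ? my : dot(xq, B.col(a2)) * sy + my;
      pred(i, a2) = yq;
    }
  }
  return pred;
}
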