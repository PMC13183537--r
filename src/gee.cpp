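// Gaussian-family GEE with identity link and exchangeable (or independence)
// working correlation, plus a fast weighted-least-squares profiler used by
// the breakpoint search. Data must arrive sorted by cluster; csize gives the
// size of each contiguous cluster block.
//
// Exchangeable algebra: R = (1-a)I + aJ, so
//   R^{-1} = 1/(1-a) * (I - a/(1+(m-1)a) J)
// and all crossproducts reduce to per-cluster column sums, making each
// iteration O(n p^2) with no per-cluster matrix inversions. The profiler
// additionally reuses the covariate blocks across candidates: only the two
// hinge columns change with K, so each candidate costs O(n p).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// per-cluster shrink factor a/(1+(m-1)a)
static inline double cfac(double alpha, unsigned int m) {
  return alpha / (1.0 + (double)(m - 1) * alpha);
}

// row -> cluster index map
static uvec row_cluster(const uvec& csize, uword n) {
  uvec cl(n);
  uword pos = 0;
  for (uword i = 0; i < csize.n_elem; ++i)
    for (uword j = 0; j < csize(i); ++j) cl(pos++) = i;
  return cl;
}

// per-cluster column sums by a single flat pass (cache friendly)
static void cluster_sums(const mat& X, const vec& y, const uvec& cl,
                         mat& S, vec& sy) {
  S.zeros();
  sy.zeros();
  const uword n = X.n_rows, p = X.n_cols;
  for (uword j = 0; j < p; ++j) {
    const double* xj = X.colptr(j);
    double* sj = S.colptr(j);
    for (uword i = 0; i < n; ++i) sj[cl(i)] += xj[i];
  }
  for (uword i = 0; i < n; ++i) sy(cl(i)) += y(i);
}

// A = X'R^{-1}X and b = X'R^{-1}y up to the common 1/(1-a) factor
static void weighted_system(const mat& XtX, const vec& Xty, const mat& S,
                            const vec& sy, const vec& cf, mat& A, vec& b) {
  A = XtX;
  b = Xty;
  if (any(cf != 0.0)) {
    A -= S.t() * (S.each_col() % cf);
    b -= S.t() * (cf % sy);
  }
}

// moment estimates of dispersion phi and exchangeable alpha from residuals
static void moment_estimates(const vec& r, const uvec& csize, uword p,
                             double& phi, double& alpha, bool exch) {
  const double n = (double)r.n_elem;
  phi = dot(r, r) / std::max(n - (double)p, 1.0);
  alpha = 0.0;
  if (!exch) return;
  double num = 0.0, npairs = 0.0;
  uword pos = 0, mmax = 1;
  for (uword i = 0; i < csize.n_elem; ++i) {
    uword m = csize(i);
    if (m > mmax) mmax = m;
    if (m > 1) {
      vec ri = r.subvec(pos, pos + m - 1);
      double s = accu(ri);
      num += 0.5 * (s * s - dot(ri, ri));
      npairs += 0.5 * (double)m * (double)(m - 1);
    }
    pos += m;
  }
  double denom = (npairs - (double)p) * phi;
  if (denom <= 0.0 || npairs <= 0.0) { alpha = 0.0; return; }
  alpha = num / denom;
  // keep R positive definite: alpha in (-1/(mmax-1), 1)
  double lo = (mmax > 1) ? (-1.0 / (double)(mmax - 1) + 1e-6) : -0.99;
  if (alpha < lo) alpha = lo;
  if (alpha > 0.99) alpha = 0.99;
}

// [[Rcpp::export(name = ".gee_fit_cpp")]]
Rcpp::List gee_fit_cpp(const arma::mat& X, const arma::vec& y,
                       const arma::uvec& csize, bool exchangeable,
                       double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols, k = csize.n_elem;
  const uvec cl = row_cluster(csize, n);
  mat XtX = X.t() * X;
  vec Xty = X.t() * y;
  mat S(k, p);
  vec sy(k);
  cluster_sums(X, y, cl, S, sy);

  vec cf(k, fill::zeros), beta;
  mat A;
  vec b;
  weighted_system(XtX, Xty, S, sy, cf, A, b);
  if (!solve(beta, A, b, solve_opts::no_approx))
    Rcpp::stop("rank-deficient design in GEE fit");

  double phi = 1.0, alpha = 0.0;
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxit; ++iter) {
    vec r = y - X * beta;
    moment_estimates(r, csize, p, phi, alpha, exchangeable);
    for (uword i = 0; i < k; ++i) cf(i) = cfac(alpha, csize(i));
    weighted_system(XtX, Xty, S, sy, cf, A, b);
    vec beta_new;
    if (!solve(beta_new, A, b, solve_opts::no_approx))
      Rcpp::stop("rank-deficient design in GEE fit");
    double delta = norm(beta_new - beta, "inf");
    beta = beta_new;
    if (delta < tol || !exchangeable) { converged = true; break; }
  }
  vec r = y - X * beta;
  moment_estimates(r, csize, p, phi, alpha, exchangeable);

  // sandwich: bread A = X'R^{-1}X, meat = sum_i u_i u_i',
  // u_i = X_i'R_i^{-1} r_i; the 1/(1-a) scale cancels in A^{-1} M A^{-1}
  for (uword i = 0; i < k; ++i) cf(i) = cfac(alpha, csize(i));
  weighted_system(XtX, Xty, S, sy, cf, A, b);
  mat U(k, p);   // rows u_i
  vec rsum(k, fill::zeros);
  {
    mat Sr(k, p);
    vec dummy(k);
    cluster_sums(X.each_col() % r, r, cl, Sr, rsum);
    U = Sr - (S.each_col() % (cf % rsum));
  }
  mat M = U.t() * U;
  mat Ainv = inv(A);
  mat V = Ainv * M * Ainv;

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("vbeta") = V,
    Rcpp::Named("alpha") = exchangeable ? alpha : 0.0,
    Rcpp::Named("phi") = phi,
    Rcpp::Named("rss") = dot(r, r),
    Rcpp::Named("n") = (int)n,
    Rcpp::Named("n_clusters") = (int)k,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}

// Residual sum of squares of the hinge model [Z, (f-K)-, (f-K)+] fitted by
// one WLS solve at a fixed working alpha, for each candidate K. The
// covariate blocks (Z'Z, Z'y, cluster sums of Z) are computed once; each
// candidate only updates the two hinge columns. NaN where the solve fails.
// [[Rcpp::export(name = ".hinge_rss_profile_cpp")]]
arma::vec hinge_rss_profile_cpp(const arma::mat& Z, const arma::vec& f,
                                const arma::vec& y, const arma::uvec& csize,
                                const arma::vec& Ks, double alpha) {
  const uword n = Z.n_rows, q = Z.n_cols, k = csize.n_elem;
  const uword p = q + 2;
  const uvec cl = row_cluster(csize, n);

  mat ZtZ = Z.t() * Z;
  vec Zty = Z.t() * y;
  mat Sz(k, q);
  vec sy(k);
  cluster_sums(Z, y, cl, Sz, sy);
  vec cf(k);
  for (uword i = 0; i < k; ++i) cf(i) = cfac(alpha, csize(i));
  const double yty = dot(y, y);

  // weighted covariate block, constant across candidates
  mat Azz;
  vec bz;
  weighted_system(ZtZ, Zty, Sz, sy, cf, Azz, bz);
  mat Szc = Sz.each_col() % cf;   // k x q, c_i * sz_i

  vec h1(n), h2(n), out(Ks.n_elem);
  vec s1(k), s2(k);
  for (uword j = 0; j < Ks.n_elem; ++j) {
    const double K = Ks(j);
    s1.zeros(); s2.zeros();
    double h1h1 = 0.0, h2h2 = 0.0, h1y = 0.0, h2y = 0.0;
    for (uword i = 0; i < n; ++i) {
      double d = f(i) - K;
      double a1 = d < 0 ? d : 0.0, a2 = d >= 0 ? d : 0.0;
      h1(i) = a1; h2(i) = a2;
      h1h1 += a1 * a1; h2h2 += a2 * a2;
      h1y += a1 * y(i); h2y += a2 * y(i);
      s1(cl(i)) += a1; s2(cl(i)) += a2;
    }
    vec Zh1 = Z.t() * h1, Zh2 = Z.t() * h2;

    mat A(p, p);
    vec b(p);
    A.submat(0, 0, q - 1, q - 1) = Azz;
    vec a1z = Zh1 - Szc.t() * s1;
    vec a2z = Zh2 - Szc.t() * s2;
    A.submat(0, q, q - 1, q) = a1z;
    A.submat(0, q + 1, q - 1, q + 1) = a2z;
    A.submat(q, 0, q, q - 1) = a1z.t();
    A.submat(q + 1, 0, q + 1, q - 1) = a2z.t();
    A(q, q) = h1h1 - dot(cf % s1, s1);
    A(q + 1, q + 1) = h2h2 - dot(cf % s2, s2);
    A(q, q + 1) = A(q + 1, q) = -dot(cf % s1, s2); // h1.h2 = 0 pointwise
    b.subvec(0, q - 1) = bz;
    b(q) = h1y - dot(cf % s1, sy);
    b(q + 1) = h2y - dot(cf % s2, sy);

    vec beta;
    if (!solve(beta, A, b, solve_opts::no_approx)) {
      out(j) = datum::nan;
      continue;
    }
    // unweighted RSS = y'y - 2 beta'X'y + beta'X'X beta via the same blocks
    mat XtX(p, p);
    XtX.submat(0, 0, q - 1, q - 1) = ZtZ;
    XtX.submat(0, q, q - 1, q) = Zh1;
    XtX.submat(0, q + 1, q - 1, q + 1) = Zh2;
    XtX.submat(q, 0, q, q - 1) = Zh1.t();
    XtX.submat(q + 1, 0, q + 1, q - 1) = Zh2.t();
    XtX(q, q) = h1h1;
    XtX(q + 1, q + 1) = h2h2;
    XtX(q, q + 1) = XtX(q + 1, q) = 0.0;
    vec Xty2(p);
    Xty2.subvec(0, q - 1) = Zty;
    Xty2(q) = h1y;
    Xty2(q + 1) = h2y;
    double rss = yty - 2.0 * dot(beta, Xty2) +
      as_scalar(beta.t() * XtX * beta);
    out(j) = rss < 0 ? 0.0 : rss;
  }
  return out;
}
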