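// SIMPLS partial least squares with cross-validation helpers.
// Predictors are autoscaled and the response centred inside every fit;
// returned coefficients are on the standardized-X scale.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// cumulative SIMPLS coefficient vectors for 1..ncomp components
// X, y must already be centred (and X scaled by the caller)
static mat simpls_coefs(const mat& X, const vec& y, int ncomp) {
  const int p = X.n_cols;
  vec s = X.t() * y;
  mat V(p, ncomp, fill::zeros);
  mat betas(p, ncomp, fill::zeros);
  vec beta(p, fill::zeros);
  int a_done = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec r = s;
    vec t = X * r;
    double normt = norm(t);
    if (normt < 1e-10) break;
    t /= normt; r /= normt;
    vec pl = X.t() * t;
    double q = dot(y, t);
    vec v = pl;
    if (a > 0) v -= V.cols(0, a - 1) * (V.cols(0, a - 1).t() * pl);
    double nv = norm(v);
    if (nv < 1e-10) break;
    v /= nv;
    V.col(a) = v;
    s -= v * dot(v, s);
    beta += r * q;
    betas.col(a) = beta;
    a_done = a + 1;
  }
  // pad unreached components with the last attainable solution
  for (int a = a_done; a < ncomp; ++a) betas.col(a) = beta;
  return betas;
}

// [[Rcpp::export(name = ".pls_coef")]]
arma::vec pls_coef_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  const int n = X.n_rows;
  int A = std::min((int)std::min((uword)ncomp, X.n_cols), n - 1);
  if (A < 1) Rcpp::stop("need at least one PLS component");
  rowvec mu = mean(X, 0);
  rowvec sd = stddev(X, 0, 0);
  sd.elem(find(sd < 1e-12)).fill(1.0);
  mat Xs = (X.each_row() - mu).eval();
  Xs.each_row() /= sd;
  vec yc = y - mean(y);
  mat betas = simpls_coefs(Xs, yc, A);
  return betas.col(A - 1);
}

// RMSECV for each component count 1..ncomp under the supplied fold labels
// (1-based). Autoscaling is re-estimated inside each training fold.
static vec cv_rmse_path(const mat& X, const vec& y, int ncomp,
                        const ivec& fold, int nfold) {
  const int n = X.n_rows;
  int A = std::min((int)std::min((uword)ncomp, X.n_cols), n - 2);
  if (A < 1) A = 1;
  vec sse(A, fill::zeros);
  for (int f = 1; f <= nfold; ++f) {
    uvec test = find(fold == f);
    uvec train = find(fold != f);
    if (test.n_elem == 0 || train.n_elem < 3) continue;
    mat Xtr = X.rows(train);
    vec ytr = y.elem(train);
    rowvec mu = mean(Xtr, 0);
    rowvec sd = stddev(Xtr, 0, 0);
    sd.elem(find(sd < 1e-12)).fill(1.0);
    mat Xs = (Xtr.each_row() - mu).eval();
    Xs.each_row() /= sd;
    double ymu = mean(ytr);
    int Af = std::min(A, (int)train.n_elem - 1);
    mat betas = simpls_coefs(Xs, ytr - ymu, Af);
    mat Xte = X.rows(test);
    Xte.each_row() -= mu;
    Xte.each_row() /= sd;
    for (int a = 0; a < A; ++a) {
      int ause = std::min(a, Af - 1);
      vec pred = Xte * betas.col(ause) + ymu;
      vec res = y.elem(test) - pred;
      sse(a) += dot(res, res);
    }
  }
  return sqrt(sse / (double)n);
}

// [[Rcpp::export(name = ".pls_cv_rmse")]]
arma::vec pls_cv_rmse_cpp(const arma::mat& X, const arma::vec& y, int ncomp,
                          const arma::ivec& fold) {
  int nfold = fold.max();
  return cv_rmse_path(X, y, ncomp, fold, nfold);
}

// Minimum RMSECV over the component path for every row of a binary
// inclusion matrix (models over variable subsets; IRIV workhorse).
// [[Rcpp::export(name = ".pls_cv_rmse_rows")]]
arma::vec pls_cv_rmse_rows_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::umat& inclusion, int ncomp,
                               const arma::ivec& fold) {
  int nfold = fold.max();
  const int m = inclusion.n_rows;
  vec out(m);
  for (int i = 0; i < m; ++i) {
    uvec cols = find(inclusion.row(i).t() == 1);
    if (cols.n_elem == 0) { out(i) = datum::inf; continue; }
    mat Xi = X.cols(cols);
    vec path = cv_rmse_path(Xi, y, ncomp, fold, nfold);
    out(i) = path.min();
  }
  return out;
}
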