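// Lasso path by coordinate descent with covariance updates, plus the inner
// k-fold CV used for penalty selection. Conventions follow the common
// coordinate-descent practice for the gaussian objective
//   (1/2n) * ||y - b0 - X beta||^2 + lambda * ||beta||_1
// with predictors standardized internally (mean 0, variance 1 with the 1/n
// denominator) and coefficients returned on the original scale, so results
// are directly comparable with glmnet's.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// standardize columns in place; xs[j] == 0 marks a constant column,
// which is frozen at beta_j = 0 throughout
static void standardize_cols(arma::mat& X, arma::rowvec& xm, arma::rowvec& xs) {
  xm = arma::mean(X, 0);
  X.each_row() -= xm;
  xs = arma::sqrt(arma::mean(arma::square(X), 0));
  for (arma::uword j = 0; j < X.n_cols; ++j)
    if (xs[j] > 0) X.col(j) /= xs[j];
}

// coordinate descent along a descending lambda path with warm starts and
// active-set iteration; convergence when the largest squared coordinate
// update falls below thresh * var(y) (predictors have unit variance), the
// usual objective-scaled stopping rule. Returns standardized-scale
// coefficients, one column per lambda.
static arma::mat cd_path(const arma::vec& g, const arma::mat& C,
                         const arma::uvec& ok, const arma::vec& lambda,
                         double thresh, int maxit, double vy) {
  const arma::uword p = g.n_elem, L = lambda.n_elem;
  const double tol = thresh * (vy > 0 ? vy : 1.0);
  arma::mat B(p, L, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  for (arma::uword l = 0; l < L; ++l) {
    const double lam = lambda[l];
    int it = 0;
    while (it < maxit) {
      // full sweep over all usable coordinates
      double dmax = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        if (!ok[j]) continue;
        double zj = g[j] - arma::dot(C.col(j), beta) + beta[j];
        double bnew = 0.0;
        if (zj > lam) bnew = zj - lam;
        else if (zj < -lam) bnew = zj + lam;
        double d = bnew - beta[j];
        if (d != 0.0) {
          beta[j] = bnew;
          double d2 = d * d;
          if (d2 > dmax) dmax = d2;
        }
      }
      ++it;
      if (dmax < tol) break;
      // converge on the current active set before the next full sweep
      arma::uvec active = arma::find(beta != 0.0);
      while (it < maxit) {
        double amax = 0.0;
        for (arma::uword k = 0; k < active.n_elem; ++k) {
          arma::uword j = active[k];
          double zj = g[j] - arma::dot(C.col(j), beta) + beta[j];
          double bnew = 0.0;
          if (zj > lam) bnew = zj - lam;
          else if (zj < -lam) bnew = zj + lam;
          double d = bnew - beta[j];
          if (d != 0.0) {
            beta[j] = bnew;
            double d2 = d * d;
            if (d2 > amax) amax = d2;
          }
        }
        ++it;
        if (amax < tol) break;
      }
    }
    B.col(l) = beta;
  }
  return B;
}

static arma::vec make_lambda_seq(double lmax, int nlambda, double lmr) {
  arma::vec lambda(nlambda);
  if (lmax <= 0) lmax = 1e-3;  // degenerate: no predictor correlates with y
  const double llmax = std::log(lmax), llmin = std::log(lmax * lmr);
  for (int l = 0; l < nlambda; ++l)
    lambda[l] = std::exp(llmax + (llmin - llmax) * l / (nlambda - 1.0));
  return lambda;
}

// fit the path on (X, y); lambda may be empty, in which case the sequence is
// built from lambda_max = max_j |<x_j_std, y_centered>| / n
// [[Rcpp::export(name = ".lasso_path_cpp")]]
List lasso_path_cpp(const arma::mat& X, const arma::vec& y,
                    NumericVector lambda_in, int nlambda = 100,
                    double lambda_min_ratio = 1e-3,
                    double thresh = 1e-8, int maxit = 100000) {
  const double n = X.n_rows;
  arma::mat Xs = X;
  arma::rowvec xm, xs;
  standardize_cols(Xs, xm, xs);
  const double ybar = arma::mean(y);
  arma::vec yc = y - ybar;

  arma::vec g = Xs.t() * yc / n;
  arma::uvec ok(X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j) ok[j] = xs[j] > 0;

  arma::vec lambda;
  if (lambda_in.size() > 0) {
    lambda = as<arma::vec>(lambda_in);
  } else {
    double lmax = 0.0;
    for (arma::uword j = 0; j < X.n_cols; ++j)
      if (ok[j] && std::fabs(g[j]) > lmax) lmax = std::fabs(g[j]);
    // tiny upward nudge so the path head is exactly all-zero despite
    // floating-point reordering in the gradient recomputation
    lmax *= 1.0 + 1e-9;
    lambda = make_lambda_seq(lmax, nlambda, lambda_min_ratio);
  }

  arma::mat C = Xs.t() * Xs / n;
  arma::mat Bs = cd_path(g, C, ok, lambda, thresh, maxit, arma::mean(arma::square(yc)));

  // back to the original predictor scale
  arma::mat B(Bs.n_rows, Bs.n_cols, arma::fill::zeros);
  for (arma::uword j = 0; j < Bs.n_rows; ++j)
    if (ok[j]) B.row(j) = Bs.row(j) / xs[j];
  arma::rowvec a0 = ybar - xm * B;

  return List::create(_["lambda"] = lambda,
                      _["a0"] = arma::vec(a0.t()),
                      _["beta"] = B);
}

// path on the full data plus k-fold CV curves at the same lambda sequence;
// each fold refits with its own standardization, mirroring how glmnet's
// cv routine refits on each training split
// [[Rcpp::export(name = ".lasso_cv_cpp")]]
List lasso_cv_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::ivec& foldid, int nlambda = 100,
                  double lambda_min_ratio = 1e-3,
                  double thresh = 1e-8, int maxit = 100000) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const int K = foldid.max();

  List full = lasso_path_cpp(X, y, NumericVector(0), nlambda,
                             lambda_min_ratio, thresh, maxit);
  arma::vec lambda = full["lambda"];
  const arma::uword L = lambda.n_elem;

  arma::mat errs(n, L, arma::fill::zeros);
  for (int k = 1; k <= K; ++k) {
    arma::uvec test = arma::find(foldid == k);
    arma::uvec train = arma::find(foldid != k);
    arma::mat Xt = X.rows(train);
    arma::vec yt = y(train);
    arma::rowvec xm, xs;
    standardize_cols(Xt, xm, xs);
    const double ybar = arma::mean(yt);
    arma::vec yc = yt - ybar;
    const double ntr = Xt.n_rows;
    arma::vec g = Xt.t() * yc / ntr;
    arma::uvec ok(p);
    for (arma::uword j = 0; j < p; ++j) ok[j] = xs[j] > 0;
    arma::mat C = Xt.t() * Xt / ntr;
    arma::mat Bs = cd_path(g, C, ok, lambda, thresh, maxit,
                           arma::mean(arma::square(yc)));
    arma::mat B(p, L, arma::fill::zeros);
    for (arma::uword j = 0; j < p; ++j)
      if (ok[j]) B.row(j) = Bs.row(j) / xs[j];
    arma::rowvec a0 = ybar - xm * B;

    arma::mat pred = X.rows(test) * B;
    pred.each_row() += a0;
    arma::vec ytest = y(test);
    for (arma::uword l = 0; l < L; ++l) {
      arma::vec d = pred.col(l) - ytest;
      errs(test, arma::uvec{l}) = arma::square(d);
    }
  }

  // grouped convention: collapse to per-fold mean errors, then the weighted
  // spread of fold means over (K - 1)
  arma::mat fold_mean(K, L, arma::fill::zeros);
  arma::vec fold_w(K);
  for (int k = 1; k <= K; ++k) {
    arma::uvec idx = arma::find(foldid == k);
    fold_w[k - 1] = idx.n_elem;
    fold_mean.row(k - 1) = arma::mean(errs.rows(idx), 0);
  }
  const double wtot = arma::accu(fold_w);
  arma::rowvec cvm = fold_w.t() * fold_mean / wtot;
  arma::rowvec cvsd(L);
  for (arma::uword l = 0; l < L; ++l) {
    arma::vec d = fold_mean.col(l) - cvm[l];
    cvsd[l] = std::sqrt(arma::dot(fold_w, arma::square(d)) / wtot / (K - 1.0));
  }

  arma::mat B = full["beta"];
  arma::ivec nzero(L);
  for (arma::uword l = 0; l < L; ++l)
    nzero[l] = arma::accu(B.col(l) != 0.0);

  return List::create(_["lambda"] = lambda,
                      _["cvm"] = arma::vec(cvm.t()),
                      _["cvsd"] = arma::vec(cvsd.t()),
                      _["a0"] = full["a0"],
                      _["beta"] = B,
                      _["nzero"] = nzero);
}
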