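// Pseudo-linear / pseudo-quadratic Gaussian discriminants.
//
// When a class (or pooled) covariance matrix is singular, the Moore-Penrose
// pseudoinverse is used, so training never fails on degenerate feature
// subsets (constant columns, n < p folds). The log-determinant term uses the
// pseudo-determinant (product of retained eigenvalues).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ClassParams {
  arma::vec mu;
  arma::mat winv;     // pseudoinverse of covariance
  double logdet;      // log pseudo-determinant
  double logprior;
};

static void pseudo_inv_sym(const arma::mat& S, arma::mat& winv,
                           double& logdet) {
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, arma::symmatu(S));
  const double tol = eval.n_elem > 0
    ? arma::datum::eps * eval.max() * (double)eval.n_elem : 0.0;
  arma::vec inv_eval(eval.n_elem, arma::fill::zeros);
  logdet = 0.0;
  for (arma::uword i = 0; i < eval.n_elem; ++i) {
    if (eval(i) > tol && eval(i) > 0.0) {
      inv_eval(i) = 1.0 / eval(i);
      logdet += std::log(eval(i));
    }
  }
  winv = evec * arma::diagmat(inv_eval) * evec.t();
}

static arma::mat class_cov(const arma::mat& X, const arma::vec& mu) {
  const double n = (double)X.n_rows;
  if (n < 2.0) return arma::mat(X.n_cols, X.n_cols, arma::fill::zeros);
  arma::mat C = X.each_row() - mu.t();
  return (C.t() * C) / (n - 1.0);
}

static std::vector<ClassParams> fit_gauss(const arma::mat& X,
                                          const arma::ivec& y,
                                          bool quadratic) {
  arma::uvec idx0 = arma::find(y == 0);
  arma::uvec idx1 = arma::find(y == 1);
  if (idx0.n_elem == 0 || idx1.n_elem == 0)
    stop("both classes must be present to fit a discriminant");
  const double n = (double)y.n_elem;
  arma::mat X0 = X.rows(idx0), X1 = X.rows(idx1);
  std::vector<ClassParams> par(2);
  par[0].mu = arma::mean(X0, 0).t();
  par[1].mu = arma::mean(X1, 0).t();
  par[0].logprior = std::log((double)idx0.n_elem / n);
  par[1].logprior = std::log((double)idx1.n_elem / n);
  arma::mat S0 = class_cov(X0, par[0].mu);
  arma::mat S1 = class_cov(X1, par[1].mu);
  if (quadratic) {
    pseudo_inv_sym(S0, par[0].winv, par[0].logdet);
    pseudo_inv_sym(S1, par[1].winv, par[1].logdet);
  } else {
    const double n0 = (double)idx0.n_elem, n1 = (double)idx1.n_elem;
    double denom = n0 + n1 - 2.0;
    if (denom < 1.0) denom = 1.0;
    arma::mat Sp = ((n0 - 1.0) * S0 + (n1 - 1.0) * S1) / denom;
    arma::mat winv;
    double logdet;
    pseudo_inv_sym(Sp, winv, logdet);
    par[0].winv = winv; par[1].winv = winv;
    par[0].logdet = logdet; par[1].logdet = logdet;
  }
  return par;
}

// per-sample discriminant scores (log posterior up to a shared constant)
static arma::mat score_gauss(const std::vector<ClassParams>& par,
                             const arma::mat& X) {
  arma::mat out(X.n_rows, 2);
  for (int c = 0; c < 2; ++c) {
    arma::mat C = X.each_row() - par[c].mu.t();
    arma::vec q = arma::sum((C * par[c].winv) % C, 1);
    out.col(c) = par[c].logprior - 0.5 * par[c].logdet - 0.5 * q;
  }
  return out;
}

// [[Rcpp::export(rng = false)]]
List gauss_disc_fit_cpp(const arma::mat& X, const arma::ivec& y,
                        bool quadratic) {
  std::vector<ClassParams> par = fit_gauss(X, y, quadratic);
  return List::create(
    _["mu0"] = par[0].mu, _["mu1"] = par[1].mu,
    _["winv0"] = par[0].winv, _["winv1"] = par[1].winv,
    _["logdet0"] = par[0].logdet, _["logdet1"] = par[1].logdet,
    _["logprior0"] = par[0].logprior, _["logprior1"] = par[1].logprior,
    _["quadratic"] = quadratic);
}

// [[Rcpp::export(rng = false)]]
NumericMatrix gauss_disc_score_cpp(const List& fit, const arma::mat& X) {
  std::vector<ClassParams> par(2);
  par[0].mu = as<arma::vec>(fit["mu0"]);
  par[1].mu = as<arma::vec>(fit["mu1"]);
  par[0].winv = as<arma::mat>(fit["winv0"]);
  par[1].winv = as<arma::mat>(fit["winv1"]);
  par[0].logdet = as<double>(fit["logdet0"]);
  par[1].logdet = as<double>(fit["logdet1"]);
  par[0].logprior = as<double>(fit["logprior0"]);
  par[1].logprior = as<double>(fit["logprior1"]);
  return wrap(score_gauss(par, X));
}

// Cross-validated misclassification error of a Gaussian discriminant on a
// column subset, over pre-built (already over-sampled) training folds.
// cols are 0-based column indices into the fold matrices.
// [[Rcpp::export(rng = false)]]
double cv_mce_gauss_cpp(const List& train_X, const List& train_y,
                        const List& val_X, const List& val_y,
                        const arma::uvec& cols, bool quadratic) {
  const int nf = train_X.size();
  double errs = 0.0, total = 0.0;
  for (int f = 0; f < nf; ++f) {
    arma::mat Xtr = as<arma::mat>(train_X[f]);
    arma::ivec ytr = as<arma::ivec>(train_y[f]);
    arma::mat Xva = as<arma::mat>(val_X[f]);
    arma::ivec yva = as<arma::ivec>(val_y[f]);
    std::vector<ClassParams> par = fit_gauss(Xtr.cols(cols), ytr, quadratic);
    arma::mat sc = score_gauss(par, Xva.cols(cols));
    for (arma::uword i = 0; i < yva.n_elem; ++i) {
      int pred = sc(i, 1) > sc(i, 0) ? 1 : 0;
      if (pred != yva(i)) errs += 1.0;
      total += 1.0;
    }
  }
  return total > 0.0 ? errs / total : NA_REAL;
}
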