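// Ridge-penalized logistic regression by iteratively reweighted least
// squares with step-halving, on an index-coded binary design: idx is an
// m x n integer matrix with one RECORD PER COLUMN, holding ASCENDING 1-based
// design-column indices (0 = unused slot). Design column 1 is the intercept
// and is never penalized. The representation exploits that every row of a
// triage indicator design has only ~10 active columns, so X'WX accumulates
// in O(n * m^2) instead of O(n * p^2); the column-per-record layout keeps
// each record's indices contiguous in memory. Each iteration makes a single
// pass over the data that yields the penalized deviance AND the Newton
// system at the current coefficients; step-halving on the deviance keeps
// Newton stable under quasi-separation (rare indicator columns with no
// events) and under warm starts, and an optional glm-style relative-
// deviance stopping rule avoids grinding runaway separated coefficients to
// full step precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

struct FitResult {
  arma::vec beta;
  bool converged;
  int iterations;
  double last_step;
  double objective;
};

// One pass: penalized negative log-likelihood at beta, plus X'WX (lower
// triangle of A, intercept row/col included) and X'Wz. Requires ascending
// index sets per record so the accumulation stays in the lower triangle.
static double fused_pass(const int* ix, int m, int n, const double* y,
                         const arma::vec& beta, double ridge,
                         arma::mat& A, arma::vec& rhs, int* act) {
  A.zeros();
  rhs.zeros();
  double nll = 0.0;
  for (int i = 0; i < n; ++i) {
    const int* col = ix + (std::size_t)i * m;
    double eta = 0.0;
    int r = 0;
    for (int j = 0; j < m; ++j) {
      const int c = col[j];
      if (c > 0) {
        act[r++] = c - 1;
        eta += beta(c - 1);
      }
    }
    double mu, softplus;
    if (eta > 0) {
      const double e = std::exp(-eta);
      mu = 1.0 / (1.0 + e);
      softplus = eta + std::log1p(e);
    } else {
      const double e = std::exp(eta);
      mu = e / (1.0 + e);
      softplus = std::log1p(e);
    }
    nll += softplus - y[i] * eta;
    double w = mu * (1.0 - mu);
    if (w < 1e-10) w = 1e-10;
    const double rz = w * eta + (y[i] - mu);
    for (int a = 0; a < r; ++a) {
      rhs(act[a]) += rz;
      double* Acol = A.colptr(act[a]);
      for (int b = a; b < r; ++b) Acol[act[b]] += w;
    }
  }
  double pen = 0.0;
  for (arma::uword j = 1; j < beta.n_elem; ++j) pen += beta(j) * beta(j);
  return nll + 0.5 * ridge * pen;
}

static FitResult fit_core(const int* ix, int m, int n, const double* y,
                          int p, double ridge, int maxit, double tol,
                          double dev_tol, const arma::vec* beta_init) {
  arma::vec beta(p, arma::fill::zeros);
  if (beta_init) {
    beta = *beta_init;
  } else {
    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
    beta(0) = std::log(ybar / (1.0 - ybar));
  }

  arma::mat A(p, p), A_try(p, p);
  arma::vec rhs(p), rhs_try(p);
  std::vector<int> act(m);
  double obj = fused_pass(ix, m, n, y, beta, ridge, A, rhs, act.data());
  FitResult res{beta, false, 0, R_PosInf, obj};

  for (int iter = 1; iter <= maxit; ++iter) {
    res.iterations = iter;
    arma::mat Asym = arma::symmatl(A);
    for (int j = 1; j < p; ++j) Asym(j, j) += ridge;
    // (X'WX + ridge I) nb = X'Wz is the exact penalized Newton target: the
    // ridge terms of the gradient and the Hessian offset cancel.
    arma::vec nb;
    const bool ok = arma::solve(nb, Asym, rhs,
                                arma::solve_opts::likely_sympd +
                                arma::solve_opts::no_approx);
    if (!ok) {
      stop("logistic fit failed: singular information matrix "
           "(possible complete separation); use ridge > 0");
    }

    arma::vec step = nb - beta;
    double t = 1.0;
    arma::vec cand = beta + step;
    double obj_new = fused_pass(ix, m, n, y, cand, ridge, A_try, rhs_try,
                                act.data());
    int halvings = 0;
    const double accept_tol = 1e-10 * (1.0 + std::fabs(obj));
    while (obj_new > obj + accept_tol && halvings < 20) {
      t *= 0.5;
      cand = beta + t * step;
      obj_new = fused_pass(ix, m, n, y, cand, ridge, A_try, rhs_try,
                           act.data());
      ++halvings;
    }
    res.last_step = arma::abs(cand - beta).max();
    const double obj_drop = obj - obj_new;
    beta = cand;
    obj = obj_new;
    A = A_try;  // Newton system at the accepted point, ready for reuse
    rhs = rhs_try;
    if (res.last_step < tol ||
        (dev_tol > 0.0 && halvings == 0 &&
         obj_drop < dev_tol * (std::fabs(obj) + 0.1))) {
      res.converged = true;
      break;
    }
  }
  res.beta = beta;
  res.objective = obj;
  return res;
}

// [[Rcpp::export]]
List irls_fit_idx(const IntegerMatrix& idx, const NumericVector& y, int p,
                  double ridge, int maxit, double tol,
                  Nullable<NumericVector> beta_init = R_NilValue,
                  double dev_tol = 0.0) {
  const int m = idx.nrow(), n = idx.ncol();
  if (y.size() != n) stop("outcome length does not match design records");
  arma::vec b0;
  const arma::vec* init = nullptr;
  if (beta_init.isNotNull()) {
    NumericVector bi(beta_init);
    if (bi.size() != p) stop("beta_init length must equal p");
    b0 = arma::vec(bi.begin(), p);
    init = &b0;
  }
  FitResult res = fit_core(idx.begin(), m, n, REAL(y), p, ridge, maxit, tol,
                           dev_tol, init);
  return List::create(
    _["coefficients"] = NumericVector(res.beta.begin(), res.beta.end()),
    _["converged"] = res.converged,
    _["iterations"] = res.iterations,
    _["last_step"] = res.last_step,
    _["objective"] = res.objective,
    _["max_abs_coef"] = arma::abs(res.beta).max());
}

// Full k-fold CV in one call: fits each training split and fills the
// held-out out-of-fold probabilities. Fold 1 starts cold; later folds warm-
// start from fold 1's coefficients clamped to [-3, 3] (a quasi-separated
// coefficient from one fold can be far from another fold's optimum and
// would force step-halving there).
// [[Rcpp::export]]
List cv_oof_idx(const IntegerMatrix& idx, const NumericVector& y,
                const IntegerVector& folds, int k, int p, double ridge,
                int maxit, double tol, double dev_tol) {
  const int m = idx.nrow(), n = idx.ncol();
  if (y.size() != n || folds.size() != n) {
    stop("outcome/fold length does not match design records");
  }
  NumericVector oof(n);
  IntegerVector iterations(k);
  LogicalVector converged(k);
  std::vector<int> train_ix((std::size_t)m * n);
  std::vector<double> train_y(n);
  arma::vec warm;
  const int* ix = idx.begin();

  for (int f = 1; f <= k; ++f) {
    int ntr = 0;
    for (int i = 0; i < n; ++i) {
      if (folds[i] != f) {
        std::memcpy(train_ix.data() + (std::size_t)ntr * m,
                    ix + (std::size_t)i * m, m * sizeof(int));
        train_y[ntr] = y[i];
        ++ntr;
      }
    }
    FitResult res = fit_core(train_ix.data(), m, ntr, train_y.data(), p,
                             ridge, maxit, tol, dev_tol,
                             f == 1 ? nullptr : &warm);
    iterations[f - 1] = res.iterations;
    converged[f - 1] = res.converged;
    if (!res.converged) {
      return List::create(_["oof"] = oof, _["converged"] = converged,
                          _["iterations"] = iterations,
                          _["failed_fold"] = f);
    }
    if (f == 1) warm = arma::clamp(res.beta, -3.0, 3.0);
    for (int i = 0; i < n; ++i) {
      if (folds[i] == f) {
        const int* col = ix + (std::size_t)i * m;
        double eta = 0.0;
        for (int j = 0; j < m; ++j) {
          const int c = col[j];
          if (c > 0) eta += res.beta(c - 1);
        }
        oof[i] = 1.0 / (1.0 + std::exp(-eta));
      }
    }
  }
  return List::create(_["oof"] = oof, _["converged"] = converged,
                      _["iterations"] = iterations, _["failed_fold"] = 0);
}

// [[Rcpp::export]]
NumericVector predict_prob_idx(const IntegerMatrix& idx,
                               const NumericVector& beta) {
  const int m = idx.nrow(), n = idx.ncol();
  NumericVector out(n);
  const int* ix = idx.begin();
  for (int i = 0; i < n; ++i) {
    const int* col = ix + (std::size_t)i * m;
    double eta = 0.0;
    for (int j = 0; j < m; ++j) {
      const int c = col[j];
      if (c > 0) eta += beta[c - 1];
    }
    out[i] = 1.0 / (1.0 + std::exp(-eta));
  }
  return out;
}
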