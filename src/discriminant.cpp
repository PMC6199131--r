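// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Penalised logistic regression by iteratively reweighted least squares.
// Model: p = sigmoid(b + X w); ridge penalty lambda on w only (never on b).
// Convergence: max |delta beta| < tol or maxit iterations.
// Penalised Bernoulli log-likelihood, computed stably via log1p.
static double pen_loglik(const arma::mat &Xa, const arma::vec &y,
                         const arma::vec &pen, const arma::vec &beta) {
  arma::vec eta = Xa * beta;
  double ll = 0.0;
  for (arma::uword i = 0; i < eta.n_elem; ++i) {
    double e = eta(i);
    ll += y(i) * e - (e > 30 ? e : std::log1p(std::exp(e)));
  }
  return ll - 0.5 * arma::dot(pen, beta % beta);
}

static arma::vec irls_fit(const arma::mat &X, const arma::vec &y,
                          double lambda, int maxit, double tol,
                          const arma::vec &beta0) {
  int n = X.n_rows, d = X.n_cols;
  arma::mat Xa(n, d + 1);
  Xa.col(0).ones();
  Xa.cols(1, d) = X;
  arma::vec beta = beta0;
  arma::vec pen(d + 1, arma::fill::value(lambda));
  pen(0) = 0.0;
  double ll = pen_loglik(Xa, y, pen, beta);
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = Xa * beta;
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    p = arma::clamp(p, 1e-10, 1.0 - 1e-10);
    arma::vec w = p % (1.0 - p);
    arma::vec grad = Xa.t() * (y - p) - pen % beta;
    arma::mat H = Xa.t() * (Xa.each_col() % w);
    H.diag() += pen;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd +
                                             arma::solve_opts::no_approx);
    if (!ok) {
      H.diag() += 1e-8 * (arma::trace(H) / (d + 1));
      step = arma::solve(H, grad);
    }
    // Newton step with halving: never accept a step that lowers the
    // penalised likelihood (guards separable / ill-conditioned windows).
    double ll_new = pen_loglik(Xa, y, pen, beta + step);
    int halvings = 0;
    while (ll_new < ll && halvings < 30) {
      step *= 0.5;
      ll_new = pen_loglik(Xa, y, pen, beta + step);
      ++halvings;
    }
    if (ll_new < ll) break;              // no improving step left
    beta += step;
    ll = ll_new;
    if (arma::abs(step).max() < tol) break;
  }
  return beta;
}

// [[Rcpp::export]]
NumericVector irls_logistic_cpp(const arma::mat &X, const arma::vec &y,
                                double lambda, int maxit, double tol) {
  arma::vec beta0(X.n_cols + 1, arma::fill::zeros);
  arma::vec beta = irls_fit(X, y, lambda, maxit, tol, beta0);
  return wrap(beta);
}

// Leave-one-out decision values: for each trial, refit on the n-1 others
// (warm-started from the full-data solution) and score the held-out trial.
// [[Rcpp::export]]
NumericVector loo_scores_cpp(const arma::mat &X, const arma::vec &y,
                             double lambda, int maxit, double tol) {
  int n = X.n_rows, d = X.n_cols;
  arma::vec beta0(d + 1, arma::fill::zeros);
  arma::vec beta_full = irls_fit(X, y, lambda, maxit, tol, beta0);
  NumericVector out(n);
  arma::uvec all = arma::regspace<arma::uvec>(0, n - 1);
  for (int i = 0; i < n; ++i) {
    arma::uvec keep = arma::find(all != (unsigned)i);
    arma::vec beta = irls_fit(X.rows(keep), y.elem(keep), lambda, maxit, tol,
                              beta_full);
    out[i] = beta(0) + arma::dot(X.row(i).t(), beta.subvec(1, d));
  }
  return out;
}

// Area under the ROC curve by trapezoidal integration of the empirical ROC,
// sweeping score thresholds from high to low; tied scores advance TPR and
// FPR together so ties contribute half credit.
// [[Rcpp::export]]
double az_roc_cpp(const arma::vec &scores, const arma::ivec &labels) {
  int n = scores.n_elem;
  arma::uvec ord = arma::sort_index(scores, "descend");
  double n_pos = 0, n_neg = 0;
  for (int i = 0; i < n; ++i) (labels[i] == 1 ? n_pos : n_neg)++;
  if (n_pos == 0 || n_neg == 0) return NA_REAL;
  double tp = 0, fp = 0, auc = 0, tp_prev = 0, fp_prev = 0;
  int i = 0;
  while (i < n) {
    double s = scores[ord[i]];
    while (i < n && scores[ord[i]] == s) {
      if (labels[ord[i]] == 1) tp++; else fp++;
      ++i;
    }
    auc += (fp - fp_prev) * (tp + tp_prev) / 2.0;  // trapezoid
    tp_prev = tp;
    fp_prev = fp;
  }
  return auc / (n_pos * n_neg);
}

// Permutation null for the leave-one-out Az: shuffle labels (Fisher-Yates on
// R's RNG so set.seed() governs), run the identical LOO procedure, record Az.
// [[Rcpp::export]]
NumericVector perm_loo_az_cpp(const arma::mat &X, const arma::vec &y,
                              int n_perm, double lambda, int maxit,
                              double tol) {
  int n = X.n_rows;
  NumericVector az(n_perm);
  arma::vec yp = y;
  for (int p = 0; p < n_perm; ++p) {
    yp = y;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(yp[i], yp[j]);
    }
    NumericVector sc = loo_scores_cpp(X, yp, lambda, maxit, tol);
    arma::vec s(sc.begin(), n, false);
    arma::ivec lab(n);
    for (int i = 0; i < n; ++i) lab[i] = (int)yp[i];
    az[p] = az_roc_cpp(s, lab);
  }
  return az;
}
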