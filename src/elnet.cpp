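// Coordinate-descent solver for elastic-net penalized logistic regression.
//
// Minimizes (1/N) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ]
//             + lambda * [ (1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1 ]
// with eta = b0 + X * beta and an unpenalized intercept, by cyclic
// coordinate descent on the IRLS-weighted quadratic approximation with
// soft thresholding. Columns of X are assumed pre-standardized by the
// caller; no internal re-standardization is performed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double WMIN = 1e-5;   // floor on IRLS weights (glmnet-style)

// average negative log-likelihood (no penalty)
static double avg_nll(const mat &X, const vec &y, double b0, const vec &beta) {
  vec eta = b0 + X * beta;
  const double N = (double)y.n_elem;
  double loss = 0.0;
  for (uword i = 0; i < eta.n_elem; i++) {
    double e = eta[i];
    double l = e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    loss += l - y[i] * e;
  }
  return loss / N;
}

static double penalty(const vec &beta, double alpha, double lambda) {
  return lambda * ((1.0 - alpha) / 2.0 * dot(beta, beta) +
                   alpha * norm(beta, 1));
}

static double objective(const mat &X, const vec &y, double b0, const vec &beta,
                        double alpha, double lambda) {
  return avg_nll(X, y, b0, beta) + penalty(beta, alpha, lambda);
}

// Max violation of the stationarity conditions of the true (non-quadratic)
// objective; 0 at the exact optimum.
static double kkt_residual(const mat &X, const vec &y, double b0,
                           const vec &beta, double alpha, double lambda) {
  const double N = (double)y.n_elem;
  vec eta = b0 + X * beta;
  vec p = 1.0 / (1.0 + exp(-eta));
  vec g = X.t() * (y - p) / N;            // negative loss gradient wrt beta
  double res = std::fabs(accu(y - p) / N); // intercept stationarity
  for (uword j = 0; j < beta.n_elem; j++) {
    double gj = g[j] - lambda * (1.0 - alpha) * beta[j];
    if (beta[j] == 0.0)
      res = std::max(res, std::max(0.0, std::fabs(gj) - lambda * alpha));
    else
      res = std::max(res, std::fabs(gj - lambda * alpha * (beta[j] > 0 ? 1.0 : -1.0)));
  }
  return res;
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// One pass of coordinate updates over the index set `idx` on the weighted
// quadratic subproblem; returns the largest absolute parameter change.
static double cd_pass(const mat &X, const vec &w, vec &r, vec &beta,
                      double &b0, const vec &xwx, double wsum, double N,
                      double alpha, double lambda, const uvec &idx) {
  const uword n = X.n_rows;
  double maxdiff = 0.0;
  for (uword k = 0; k < idx.n_elem; k++) {
    const uword j = idx[k];
    const double *xj = X.colptr(j);
    double u = 0.0;
    for (uword i = 0; i < n; i++) u += xj[i] * w[i] * r[i];
    u = u / N + xwx[j] * beta[j];
    double bnew = soft(u, lambda * alpha) / (xwx[j] + lambda * (1.0 - alpha));
    double d = bnew - beta[j];
    if (d != 0.0) {
      for (uword i = 0; i < n; i++) r[i] -= xj[i] * d;
      beta[j] = bnew;
      maxdiff = std::max(maxdiff, std::fabs(d));
    }
  }
  double num = 0.0;
  for (uword i = 0; i < n; i++) num += w[i] * r[i];
  double db0 = num / wsum;
  if (db0 != 0.0) {
    b0 += db0;
    for (uword i = 0; i < n; i++) r[i] -= db0;
    maxdiff = std::max(maxdiff, std::fabs(db0));
  }
  return maxdiff;
}

// One full solve at fixed (alpha, lambda), warm-started from (b0, beta).
// Returns true if converged.
static bool solve_one(const mat &X, const vec &y, double alpha, double lambda,
                      double &b0, vec &beta, double tol, int max_outer,
                      double kkt_tol) {
  const uword n = X.n_rows, pdim = X.n_cols;
  const double N = (double)n;
  const uvec all_idx = regspace<uvec>(0, pdim - 1);
  double f_prev = objective(X, y, b0, beta, alpha, lambda);
  for (int outer = 0; outer < max_outer; outer++) {
    // IRLS weights and working response at the current linear predictor
    vec eta = b0 + X * beta;
    vec prob = 1.0 / (1.0 + exp(-eta));
    vec w(n), z(n);
    for (uword i = 0; i < n; i++) {
      double wi = prob[i] * (1.0 - prob[i]);
      if (wi < WMIN) wi = WMIN;
      w[i] = wi;
      z[i] = eta[i] + (y[i] - prob[i]) / wi;
    }
    vec xwx(pdim);
    for (uword j = 0; j < pdim; j++)
      xwx[j] = dot(square(X.col(j)), w) / N;
    double wsum = accu(w);

    double b0_old = b0;
    vec beta_old = beta;

    // inner coordinate descent: alternate full passes with passes over the
    // active (non-zero) set until a full pass changes nothing material
    vec r = z - b0 - X * beta;
    double inner_tol = std::min(tol, 1e-8);
    for (int cycle = 0; cycle < 50; cycle++) {
      double d_full = cd_pass(X, w, r, beta, b0, xwx, wsum, N, alpha,
                              lambda, all_idx);
      if (d_full < inner_tol) break;
      uvec active = find(beta != 0.0);
      for (int sweep = 0; sweep < 1000; sweep++) {
        double d = cd_pass(X, w, r, beta, b0, xwx, wsum, N, alpha, lambda,
                           active);
        if (d < inner_tol) break;
      }
    }

    // objective guard: IRLS steps may overshoot on the true objective;
    // back-track halfway toward the previous iterate until non-increasing
    double f_new = objective(X, y, b0, beta, alpha, lambda);
    int halvings = 0;
    while (f_new > f_prev + 1e-13 && halvings < 40) {
      b0 = 0.5 * (b0 + b0_old);
      beta = 0.5 * (beta + beta_old);
      f_new = objective(X, y, b0, beta, alpha, lambda);
      halvings++;
    }

    double step = std::fabs(b0 - b0_old);
    for (uword j = 0; j < pdim; j++)
      step = std::max(step, std::fabs(beta[j] - beta_old[j]));
    f_prev = f_new;
    if (step < tol &&
        kkt_residual(X, y, b0, beta, alpha, lambda) < kkt_tol)
      return true;
  }
  return kkt_residual(X, y, b0, beta, alpha, lambda) < kkt_tol;
}

// [[Rcpp::export]]
Rcpp::List cpp_elnet_logistic_path(const arma::mat &X, const arma::vec &y,
                                   double alpha, const arma::vec &lambdas,
                                   double tol = 1e-7, int max_outer = 250,
                                   double kkt_tol = 1e-6,
                                   double dev_ratio_max = 0.999) {
  const uword pdim = X.n_cols, nlam = lambdas.n_elem;
  mat betas(pdim, nlam, fill::zeros);
  vec intercepts(nlam), objectives(nlam);
  Rcpp::LogicalVector converged(nlam);

  // warm start at the null model
  double ybar = mean(y);
  if (ybar <= 0.0 || ybar >= 1.0)
    Rcpp::stop("degenerate labels: both classes must be present");
  double b0 = std::log(ybar / (1.0 - ybar));
  vec beta(pdim, fill::zeros);
  const double null_loss = avg_nll(X, y, b0, beta);

  for (uword k = 0; k < nlam; k++) {
    bool ok = solve_one(X, y, alpha, lambdas[k], b0, beta, tol, max_outer,
                        kkt_tol);
    // snap numerically-dead coordinates to exact zero
    for (uword j = 0; j < pdim; j++)
      if (std::fabs(beta[j]) < 1e-12) beta[j] = 0.0;
    betas.col(k) = beta;
    intercepts[k] = b0;
    double loss = avg_nll(X, y, b0, beta);
    objectives[k] = loss + penalty(beta, alpha, lambdas[k]);
    converged[k] = ok;
    // deviance saturation: on (near-)separable data the remaining path
    // adds no discrimination; extend the current solution and stop
    if (null_loss > 0 && (1.0 - loss / null_loss) > dev_ratio_max &&
        k + 1 < nlam) {
      for (uword k2 = k + 1; k2 < nlam; k2++) {
        betas.col(k2) = beta;
        intercepts[k2] = b0;
        objectives[k2] = loss + penalty(beta, alpha, lambdas[k2]);
        converged[k2] = ok;
      }
      break;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("intercepts") = intercepts, Rcpp::Named("betas") = betas,
      Rcpp::Named("objectives") = objectives,
      Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
double cpp_elnet_objective(const arma::mat &X, const arma::vec &y, double b0,
                           const arma::vec &beta, double alpha,
                           double lambda) {
  return objective(X, y, b0, beta, alpha, lambda);
}

// [[Rcpp::export]]
double cpp_elnet_kkt(const arma::mat &X, const arma::vec &y, double b0,
                     const arma::vec &beta, double alpha, double lambda) {
  return kkt_residual(X, y, b0, beta, alpha, lambda);
}
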