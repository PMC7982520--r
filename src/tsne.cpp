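// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-row bisection for the Gaussian bandwidths sigma_i: find beta =
// 1/(2 sigma_i^2) such that the Shannon perplexity exp(H) of the
// conditional affinity row matches the target, using the numerically
// stable form H = log(sum_j exp(-beta d_j)) + beta * E[d].
// [[Rcpp::export]]
List cpp_cond_affinities(const arma::mat& D2, double perplexity,
                         double tol, int max_iter) {
  const arma::uword n = D2.n_rows;
  arma::mat P(n, n, arma::fill::zeros);
  arma::vec sigmas(n);
  const double log_target = std::log(perplexity);

  for (arma::uword i = 0; i < n; ++i) {
    arma::rowvec d = D2.row(i);      // contiguous copy of the row
    d(i) = 0.0;
    double beta = 1.0, betamin = -arma::datum::inf,
           betamax = arma::datum::inf;
    arma::rowvec p(n, arma::fill::zeros);
    for (int iter = 0; iter < max_iter; ++iter) {
      p = arma::exp(-beta * d);
      p(i) = 0.0;
      double sum = arma::accu(p);
      if (sum <= 0) sum = DBL_MIN;
      double H = std::log(sum) + beta * arma::dot(d, p) / sum;
      double diff = H - log_target;
      if (std::fabs(diff) < tol) break;
      if (diff > 0) {                // entropy too high -> sharpen
        betamin = beta;
        beta = std::isfinite(betamax) ? (beta + betamax) / 2 : beta * 2;
      } else {
        betamax = beta;
        beta = std::isfinite(betamin) ? (beta + betamin) / 2 : beta / 2;
      }
    }
    double sum = arma::accu(p);
    if (sum <= 0) {                  // degenerate row: uniform fallback
      p.fill(1.0 / (n - 1));
      p(i) = 0.0;
      sum = 1.0;
    }
    P.row(i) = p / sum;
    sigmas(i) = std::sqrt(1.0 / (2.0 * beta));
  }
  return List::create(_["P"] = P, _["sigmas"] = sigmas);
}

// Fused Student-t kernel: W(i, j) = (1 + ||y_i - y_j||^2)^-1, zero
// diagonal. Yt is d x n (points as contiguous columns); column-major
// writes keep the pass cache-friendly.
static void student_t_weights(const arma::mat& Yt, arma::mat& W,
                              double& total) {
  const arma::uword n = Yt.n_cols, d = Yt.n_rows;
  arma::rowvec r = arma::sum(arma::square(Yt), 0);
  total = 0.0;
  for (arma::uword j = 0; j < n; ++j) {
    const double* yj = Yt.colptr(j);
    double* wj = W.colptr(j);
    const double rj = r(j);
    double colsum = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double* yi = Yt.colptr(i);
      double dot = 0.0;
      for (arma::uword k = 0; k < d; ++k) dot += yi[k] * yj[k];
      double d2 = r(i) + rj - 2.0 * dot;
      if (d2 < 0) d2 = 0;
      double w = 1.0 / (1.0 + d2);
      wj[i] = w;
      colsum += w;
    }
    wj[j] = 0.0;
    total += colsum - 1.0;           // remove the diagonal contribution
  }
}

// Student-t kernel weights and their total sum (the joint normalizer).
// [[Rcpp::export]]
List cpp_qnum(const arma::mat& Y) {
  arma::mat Yt = Y.t();
  arma::mat W(Y.n_rows, Y.n_rows);
  double total;
  student_t_weights(Yt, W, total);
  return List::create(_["W"] = W, _["sum"] = total);
}

// Gradient and cost of the symmetric (joint) t-SNE objective:
//   C = sum_ij p_ij log(p_ij / q_ij),  q_ij = w_ij / sum w
//   dC/dy_i = 4 sum_j (p_ij - q_ij) w_ij (y_i - y_j)
// q entries are floored at 1e-12 inside the log. `p_logp` is the
// iteration-invariant sum_ij p_ij log p_ij (pass NA to have it computed
// here); the caller caches it across iterations.
// [[Rcpp::export]]
List cpp_joint_grad(const arma::mat& P, const arma::mat& Y,
                    double p_logp = NA_REAL) {
  const arma::uword n = Y.n_rows, d = Y.n_cols;
  if (P.n_rows != n || P.n_cols != n)
    stop("P and Y have inconsistent sizes");
  arma::mat Yt = Y.t();              // d x n, contiguous points
  arma::mat W(n, n);
  double total;
  student_t_weights(Yt, W, total);
  if (total <= 0) total = DBL_MIN;
  const double log_total = std::log(total);
  if (!std::isfinite(p_logp)) {
    p_logp = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      const double* pj = P.colptr(j);
      for (arma::uword i = 0; i < n; ++i)
        if (pj[i] > 0) p_logp += pj[i] * std::log(pj[i]);
    }
  }
  arma::mat Gt(d, n, arma::fill::zeros);
  double p_logw = 0.0, p_sum = 0.0;
  const double inv_total = 1.0 / total;
  for (arma::uword j = 0; j < n; ++j) {
    const double* pj = P.colptr(j);
    const double* wj = W.colptr(j);
    const double* yj = Yt.colptr(j);
    double* gj = Gt.colptr(j);
    for (arma::uword i = 0; i < n; ++i) {
      if (i == j) continue;
      const double w = wj[i];
      const double p = pj[i];
      // gradient on point j from pair (i, j); P is symmetric in joint mode
      const double mult = 4.0 * (p - w * inv_total) * w;
      const double* yi = Yt.colptr(i);
      for (arma::uword k = 0; k < d; ++k)
        gj[k] += mult * (yj[k] - yi[k]);
      if (p > 0) {
        double q = w * inv_total;
        if (q < 1e-12)
          p_logw += p * (std::log(1e-12) + log_total);  // floored value
        else
          p_logw += p * std::log(w);
        p_sum += p;
      }
    }
  }
  const double cost = p_logp - p_logw + p_sum * log_total;
  return List::create(_["grad"] = Gt.t(), _["cost"] = cost);
}
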