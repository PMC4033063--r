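#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF (Frobenius norm) with optional fixed factors.
// X (M x T) is approximated by W (M x N) * H (N x T); W, H stay nonnegative
// because the updates only multiply by nonnegative ratios. `eps` guards the
// denominators against exact zeros. Iteration stops when the relative drop
// of the squared-error objective falls below `tol` (tol <= 0 forces exactly
// max_iter iterations, used for the literal fixed-iteration baselines).
// [[Rcpp::export]]
List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                const int max_iter, const double tol,
                const bool update_w, const bool update_h,
                const double eps) {
  std::vector<double> trace;
  trace.reserve(static_cast<size_t>(max_iter) + 1);
  double obj = arma::accu(arma::square(X - W * H));
  trace.push_back(obj);

  int iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    if (update_h) {
      const arma::mat num = W.t() * X;
      const arma::mat den = (W.t() * W) * H + eps;
      H %= num / den;
    }
    if (update_w) {
      const arma::mat num = X * H.t();
      const arma::mat den = W * (H * H.t()) + eps;
      W %= num / den;
    }
    const double obj_new = arma::accu(arma::square(X - W * H));
    trace.push_back(obj_new);
    iters = it;
    const double rel = std::fabs(obj - obj_new) / std::max(obj, eps);
    obj = obj_new;
    if (tol > 0.0 && rel < tol) break;
  }

  return List::create(_["W"] = W, _["H"] = H,
                      _["objective"] = obj,
                      _["objective_trace"] = trace,
                      _["n_iter"] = iters);
}
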