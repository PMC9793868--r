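// Multiplicative-update NMF for the squared-Frobenius cost.
// X (m x n) ~ W (m x r) H (r x n); W holds occurrences, H holds patterns.
// Updates (Lee-Seung) keep both factors non-negative and the cost
// non-increasing; a small epsilon guards the denominators.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      const int max_iter, const double rel_tol,
                      const double eps) {
  std::vector<double> costs;
  costs.reserve(64);
  // absolute floor: a residual this far below ||X||_F^2 is double-precision
  // noise; iterating further only churns rounding error
  const double floor_cost = 1e-20 * accu(square(X));
  double prev = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    // H <- H .* (W'X) ./ (W'W H + eps)
    H %= (W.t() * X) / (W.t() * W * H + eps);
    // W <- W .* (X H') ./ (W H H' + eps)
    W %= (X * H.t()) / (W * (H * H.t()) + eps);
    const double cost = accu(square(X - W * H));
    costs.push_back(cost);
    if (cost < floor_cost) break;
    if (prev < datum::inf && prev > 0 &&
        std::abs(prev - cost) / prev < rel_tol) break;
    prev = cost;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("cost") = costs.back(),
                            Rcpp::Named("cost_trace") = costs);
}
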