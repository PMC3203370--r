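// Multiplicative-update core for non-smooth NMF (V ~ W S H) under the
// generalized Kullback-Leibler divergence. The smoothing matrix S is
// interposed via the substitution scheme: W is replaced by W*S when
// updating H, and H by S*H when updating W, so both half-steps monotonically
// nonincrease D(V || W S H).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Generalized KL divergence D(V || R) = sum v*log(v/r) - v + r, 0*log0 = 0.
static double kl_divergence(const mat& V, const mat& R) {
  double d = 0.0;
  const double* v = V.memptr();
  const double* r = R.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (v[i] > 0.0) d += v[i] * std::log(v[i] / r[i]) - v[i];
    d += r[i];
  }
  return d;
}

// [[Rcpp::export(name = ".nsnmf_core")]]
Rcpp::List nsnmf_core(const arma::mat& V, arma::mat W, arma::mat H,
                      const arma::mat& S, int n_iter, double eps_floor,
                      double conv_tol) {
  std::vector<double> trace;
  trace.reserve(n_iter);
  double prev = datum::inf;
  int it = 0;
  for (it = 1; it <= n_iter; ++it) {
    // H update with smoothed W
    mat Ws = W * S;
    mat R = Ws * H;
    H %= Ws.t() * (V / R);
    H.each_col() /= sum(Ws, 0).t();
    H.clamp(eps_floor, datum::inf);
    // W update with smoothed H
    mat Hs = S * H;
    R = W * Hs;
    W %= (V / R) * Hs.t();
    W.each_row() /= sum(Hs, 1).t();
    W.clamp(eps_floor, datum::inf);
    double obj = kl_divergence(V, W * S * H);
    trace.push_back(obj);
    if (conv_tol > 0.0 && std::isfinite(prev)) {
      double denom = std::max(std::abs(prev), 1e-12);
      if (std::abs(prev - obj) / denom < conv_tol) break;
    }
    prev = obj;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("iterations") = (int)trace.size());
}
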