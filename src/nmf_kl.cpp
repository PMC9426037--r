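#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_divergence(const mat& V, const mat& WH) {
  // D(V || WH) = sum( V log(V/WH) - V + WH ), with 0 log 0 = 0
  double d = 0.0;
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    const double v = V(i);
    const double wh = WH(i);
    if (v > 0.0) d += v * std::log(v / wh) - v + wh;
    else d += wh;
  }
  return d;
}

// Multiplicative updates for NMF under the generalized Kullback-Leibler
// divergence (Brunet-style). W and H stay strictly positive given positive
// initialization; the objective is nonincreasing per sweep.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, int check_every) {
  const double eps = 1e-16;
  std::vector<double> trace;
  double prev = datum::inf;
  int iters = 0;
  mat WH = W * H;
  WH.for_each([eps](double& x) { if (x < eps) x = eps; });

  for (int it = 1; it <= max_iter; ++it) {
    iters = it;
    // H update
    mat Q = V / WH;
    H %= (W.t() * Q);
    vec ws = sum(W, 0).t();
    ws.for_each([eps](double& x) { if (x < eps) x = eps; });
    H.each_col() /= ws;
    WH = W * H;
    WH.for_each([eps](double& x) { if (x < eps) x = eps; });
    // W update
    Q = V / WH;
    W %= (Q * H.t());
    rowvec hs = sum(H, 1).t();
    hs.for_each([eps](double& x) { if (x < eps) x = eps; });
    W.each_row() /= hs;
    WH = W * H;
    WH.for_each([eps](double& x) { if (x < eps) x = eps; });

    if (it % check_every == 0 || it == max_iter) {
      double kl = kl_divergence(V, WH);
      trace.push_back(kl);
      double denom = std::max(std::abs(prev), 1e-12);
      if (std::isfinite(prev) && std::abs(prev - kl) / denom < tol) break;
      if (kl < 1e-12) break;
      prev = kl;
    }
  }
  double kl_final = kl_divergence(V, W * H);
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("kl") = kl_final,
                            Rcpp::Named("trace") = trace,
                            Rcpp::Named("iterations") = iters);
}
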