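#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Generalized KL divergence D(V || WH) = sum V log(V/WH) - V + WH, with
// 0*log(0) = 0. `vlogv_minus_v` = sum_{V>0} V log V - sum V is precomputed.
static double kl_objective(const arma::mat& V, const arma::mat& WH,
                           double vlogv_minus_v) {
  const double eps = 1e-16;
  const double* v = V.memptr();
  const double* wh = WH.memptr();
  const arma::uword nn = V.n_elem;
  double cross = 0.0, whsum = 0.0;
  for (arma::uword i = 0; i < nn; ++i) {
    if (v[i] > 0.0) cross += v[i] * std::log(wh[i] + eps);
    whsum += wh[i];
  }
  return vlogv_minus_v - cross + whsum;
}

// Multiplicative-update NMF under generalized KL divergence (Brunet variant).
// W and H are updated in place from the supplied initialization. The KL
// objective is evaluated every `obj_every` iterations (the update rules make
// it non-increasing, which tests assert on the returned trace with
// obj_every = 1); iteration stops when the mean per-iteration relative
// objective change between evaluations drops below `tol`.
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                int max_iter, double tol, int obj_every) {
  const double eps = 1e-16;
  if (obj_every < 1) obj_every = 1;
  double vlogv_minus_v = 0.0;
  for (arma::uword i = 0; i < V.n_elem; ++i) {
    double v = V.memptr()[i];
    if (v > 0.0) vlogv_minus_v += v * std::log(v) - v;
  }
  arma::mat WH = W * H;
  arma::mat Q(V.n_rows, V.n_cols);
  double prev = kl_objective(V, WH, vlogv_minus_v);
  std::vector<double> trace;
  std::vector<int> trace_iter;
  int it_done = 0;
  for (int it = 1; it <= max_iter; ++it) {
    // H <- H .* (W' (V ./ WH)) ./ colsums(W)'
    Q = V / (WH + eps);
    H %= W.t() * Q;
    H.each_col() /= (arma::sum(W, 0).t() + eps);
    WH = W * H;
    // W <- W .* ((V ./ WH) H') ./ rowsums(H)'
    Q = V / (WH + eps);
    W %= Q * H.t();
    W.each_row() /= (arma::sum(H, 1).t() + eps);
    WH = W * H;
    it_done = it;
    if (it % obj_every == 0 || it == max_iter) {
      double obj = kl_objective(V, WH, vlogv_minus_v);
      trace.push_back(obj);
      trace_iter.push_back(it);
      double rel = std::fabs(prev - obj) /
        ((std::fabs(prev) + 1e-10) * (double) obj_every);
      prev = obj;
      if (rel < tol) break;
    }
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["objective"] = prev,
                      _["objective_trace"] = trace,
                      _["trace_iter"] = trace_iter,
                      _["n_iter"] = it_done);
}
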