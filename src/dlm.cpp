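// Conjugate normal-gamma dynamic linear model recurrences.
//
// Per-node model: y_t = F_t' theta_t + nu_t, nu_t ~ N(0, V); V^-1 ~ Gamma.
// State evolution is handled by a single discount factor delta, i.e.
// R_t = C_{t-1} / delta. All second moments are kept on the observation
// scale (C_t includes the current point estimate S_t = d_t / n_t of V).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-time log Student-t normalising constants for df nu_t = n0 + t - 1:
// lgamma((nu+1)/2) - lgamma(nu/2) - 0.5*log(nu*pi). Shared across every
// filter run with the same prior counts and length, so precompute once.
static arma::vec t_lconst(int T, double n0) {
  arma::vec lc(T);
  for (int t = 0; t < T; ++t) {
    double nu = n0 + t;
    lc[t] = lgamma((nu + 1.0) / 2.0) - lgamma(nu / 2.0) -
            0.5 * std::log(nu * M_PI);
  }
  return lc;
}

// One full filter pass returning only the summed one-step log forecast
// density (the local LPL contribution). `lconst` must come from t_lconst.
static double filter_loglik(const arma::vec& y, const arma::mat& F,
                            const arma::vec& m0, const arma::mat& C0,
                            double n0, double d0, double delta,
                            const arma::vec& lconst) {
  const int T = y.n_elem, p = F.n_cols;
  arma::vec m = m0;
  arma::mat C = C0;
  double n = n0, d = d0, S = d0 / n0;
  double total = 0.0;
  arma::vec Fv(p), RF(p), A(p);

  for (int t = 0; t < T; ++t) {
    Fv = F.row(t).t();
    arma::mat R = C / delta;
    RF = R * Fv;
    double f = arma::dot(Fv, m);
    double q = arma::dot(Fv, RF) + S;
    if (!(q > 0.0) || !std::isfinite(q))
      stop("non-positive or non-finite forecast variance at t=%d", t + 1);
    double e = y[t] - f;
    double nu = n;  // df of the one-step forecast t-distribution
    total += lconst[t] - 0.5 * std::log(q) -
             (nu + 1.0) / 2.0 * std::log1p(e * e / (nu * q));
    A = RF / q;
    m += A * e;
    double S_old = S;
    n += 1.0;
    d += S_old * e * e / q;
    S = d / n;
    C = (S / S_old) * (R - (A * A.t()) * q);
  }
  return total;
}

// [[Rcpp::export]]
List dlm_filter_cpp(const arma::vec& y, const arma::mat& F,
                    const arma::vec& m0, const arma::mat& C0,
                    double n0, double d0, double delta) {
  const int T = y.n_elem, p = F.n_cols;
  arma::mat m_out(p, T), a_out(p, T);
  arma::cube C_out(p, p, T), R_out(p, p, T);
  arma::vec f_out(T), q_out(T), logf(T), n_out(T), d_out(T), S_out(T);
  arma::vec lconst = t_lconst(T, n0);

  arma::vec m = m0;
  arma::mat C = C0;
  double n = n0, d = d0, S = d0 / n0;

  for (int t = 0; t < T; ++t) {
    arma::vec Fv = F.row(t).t();
    arma::mat R = C / delta;
    arma::vec RF = R * Fv;
    double f = arma::dot(Fv, m);
    double q = arma::dot(Fv, RF) + S;
    if (!(q > 0.0) || !std::isfinite(q))
      stop("non-positive or non-finite forecast variance at t=%d", t + 1);
    double e = y[t] - f;
    double nu = n;
    logf[t] = lconst[t] - 0.5 * std::log(q) -
              (nu + 1.0) / 2.0 * std::log1p(e * e / (nu * q));
    a_out.col(t) = m;
    R_out.slice(t) = R;
    f_out[t] = f;
    q_out[t] = q;
    arma::vec A = RF / q;
    m += A * e;
    double S_old = S;
    n += 1.0;
    d += S_old * e * e / q;
    S = d / n;
    C = (S / S_old) * (R - (A * A.t()) * q);
    m_out.col(t) = m;
    C_out.slice(t) = C;
    n_out[t] = n;
    d_out[t] = d;
    S_out[t] = S;
  }
  return List::create(
      _["m"] = m_out, _["C"] = C_out, _["a"] = a_out, _["R"] = R_out,
      _["f"] = f_out, _["q"] = q_out, _["n"] = n_out, _["d"] = d_out,
      _["S"] = S_out, _["logf"] = logf, _["total"] = arma::accu(logf));
}

// Score a batch of parent sets (bitmasks over nodes 1..n, bit j-1 <-> node
// j) for one child node against a grid of discount factors. Returns a
// n_sets x n_deltas matrix of local LPL values.
// [[Rcpp::export]]
arma::mat score_sets_cpp(const arma::mat& Y, int r,
                         const IntegerVector& sets,
                         const NumericVector& deltas,
                         double c0_scale, double n0, double d0) {
  const int T = Y.n_rows, n = Y.n_cols;
  const int n_sets = sets.size(), n_del = deltas.size();
  arma::vec y = Y.col(r - 1);
  arma::vec lconst = t_lconst(T, n0);
  arma::mat out(n_sets, n_del);

  for (int s = 0; s < n_sets; ++s) {
    int mask = sets[s];
    if (mask & (1 << (r - 1)))
      stop("parent set for node %d contains the node itself", r);
    std::vector<int> pa;
    for (int j = 0; j < n; ++j)
      if (mask & (1 << j)) pa.push_back(j);
    const int p = 1 + (int)pa.size();
    arma::mat F(T, p, arma::fill::ones);
    for (size_t k = 0; k < pa.size(); ++k) F.col(k + 1) = Y.col(pa[k]);
    arma::vec m0(p, arma::fill::zeros);
    arma::mat C0 = c0_scale * arma::eye(p, p);
    for (int dd = 0; dd < n_del; ++dd)
      out(s, dd) = filter_loglik(y, F, m0, C0, n0, d0, deltas[dd], lconst);
  }
  return out;
}
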