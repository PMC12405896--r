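// Metropolis inner sweeps for the linear and mixed linear models.
// A sweep is `n_par` single-parameter update attempts, the parameter chosen
// uniformly at random each attempt. R-level code orchestrates the
// equilibration / accumulation phases and the stepwidth adjuster; these
// routines run a block of sweeps at fixed stepwidths and return traces.
// R's RNG is used throughout so chains are reproducible under set.seed().

#include <RcppArmadillo.h>
using namespace Rcpp;

// Linear fixed-effects model. State: beta, residual r = y - X beta,
// H = sum r_i^2 / d_i (d = diagonal of the fixed block-diagonal V).
// A single-coordinate move beta_k += delta changes H by
//   dH = -2 delta * (x_k . (r/d)) + delta^2 * w_k,  w_k = sum_i x_ik^2 / d_i,
// a rank-1 residual update.
// [[Rcpp::export]]
List sweep_linear_cpp(const arma::mat& X, const arma::vec& d,
                      const arma::vec& y, arma::vec beta,
                      int n_sweeps, double stepwidth) {
  const int n = X.n_rows, p = X.n_cols;
  arma::vec r = y - X * beta;
  arma::vec rv = r / d;
  arma::vec w(p);
  for (int k = 0; k < p; ++k) {
    arma::vec xk = X.col(k);
    w(k) = arma::dot(xk % xk, 1.0 / d);
  }
  double H = arma::dot(r, rv);
  arma::vec h_trace(n_sweeps);
  arma::ivec acc_trace(n_sweeps);
  RNGScope scope;
  for (int s = 0; s < n_sweeps; ++s) {
    int n_acc = 0;
    for (int t = 0; t < p; ++t) {
      int k = (int)std::floor(R::runif(0.0, 1.0) * p);
      if (k == p) k = p - 1;
      double delta = stepwidth * R::runif(-1.0, 1.0);
      double dH = -2.0 * delta * arma::dot(X.col(k), rv) + delta * delta * w(k);
      bool accept = dH <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dH);
      if (accept) {
        beta(k) += delta;
        r -= delta * X.col(k);
        rv = r / d;
        H += dH;
        ++n_acc;
      }
    }
    h_trace(s) = H;
    acc_trace(s) = n_acc;
  }
  return List::create(_["beta"] = beta, _["H"] = H,
                      _["h_trace"] = h_trace, _["acc_trace"] = acc_trace,
                      _["n_attempts_per_sweep"] = p);
}

struct MixedState {
  arma::mat V, L;   // covariance and its lower Cholesky factor
  double logdet;    // log |V|
};

static bool rebuild_V(const arma::mat& G, const arma::vec& s2_obs,
                      double sig_resid, MixedState& st) {
  const int n = G.n_rows;
  st.V = G * (G.each_col() % s2_obs);
  st.V.diag() += sig_resid * sig_resid;
  st.V = 0.5 * (st.V + st.V.t());
  if (!arma::chol(st.L, st.V, "lower")) return false;
  st.logdet = 2.0 * arma::sum(arma::log(st.L.diag()));
  return true;
}

static double quad_form(const MixedState& st, const arma::vec& r) {
  arma::vec z = arma::solve(arma::trimatl(st.L), r);
  return arma::dot(z, z);
}

// Mixed linear model. Parameters: beta (p), sigma_acc (q, >= 0) and
// optionally sigma_resid (> 0). H is the negative MVN log density.
// Beta moves change only the residual; sigma moves trigger a rebuild of V
// and its Cholesky factor. Proposals driving a scale negative are invalid
// and count as rejections.
// [[Rcpp::export]]
List sweep_mixed_cpp(const arma::mat& X, const arma::mat& G,
                     const arma::ivec& acc_index, // 0-based obs -> accession
                     const arma::vec& y,
                     arma::vec beta, arma::vec sigma_acc, double sigma_resid,
                     int n_sweeps, double step_beta, double step_sigma,
                     bool sample_sigma, bool sample_resid) {
  const int n = X.n_rows, p = X.n_cols, q = sigma_acc.n_elem;
  const int n_par = p + (sample_sigma ? q : 0) + (sample_resid ? 1 : 0);
  arma::vec s2_obs(n);
  for (int i = 0; i < n; ++i) s2_obs(i) = sigma_acc(acc_index(i)) * sigma_acc(acc_index(i));
  MixedState st;
  if (!rebuild_V(G, s2_obs, sigma_resid, st))
    stop("initial mixed-model covariance is not positive definite");
  arma::vec r = y - X * beta;
  const double cst = 0.5 * n * std::log(2.0 * M_PI);
  double H = 0.5 * quad_form(st, r) + cst + 0.5 * st.logdet;
  arma::vec h_trace(n_sweeps);
  arma::ivec acc_beta_trace(n_sweeps), acc_sigma_trace(n_sweeps);
  arma::ivec att_beta_trace(n_sweeps), att_sigma_trace(n_sweeps);
  RNGScope scope;
  for (int s = 0; s < n_sweeps; ++s) {
    int nab = 0, nas = 0, attb = 0, atts = 0;
    for (int t = 0; t < n_par; ++t) {
      int k = (int)std::floor(R::runif(0.0, 1.0) * n_par);
      if (k == n_par) k = n_par - 1;
      if (k < p) { // beta move
        ++attb;
        double delta = step_beta * R::runif(-1.0, 1.0);
        arma::vec r_new = r - delta * X.col(k);
        double H_new = 0.5 * quad_form(st, r_new) + cst + 0.5 * st.logdet;
        double dH = H_new - H;
        if (dH <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dH)) {
          beta(k) += delta; r = r_new; H = H_new; ++nab;
        }
      } else { // sigma move
        ++atts;
        int j = k - p;
        bool is_resid = sample_resid && (j == (sample_sigma ? q : 0));
        double delta = step_sigma * R::runif(-1.0, 1.0);
        double cur = is_resid ? sigma_resid : sigma_acc(j);
        double prop = cur + delta;
        if (prop < 0.0 || (is_resid && prop <= 0.0)) continue; // invalid
        MixedState st_new;
        arma::vec s2_new = s2_obs;
        if (is_resid) {
          if (!rebuild_V(G, s2_obs, prop, st_new)) continue;
        } else {
          for (int i = 0; i < n; ++i)
            if (acc_index(i) == j) s2_new(i) = prop * prop;
          if (!rebuild_V(G, s2_new, sigma_resid, st_new)) continue;
        }
        double H_new = 0.5 * quad_form(st_new, r) + cst + 0.5 * st_new.logdet;
        double dH = H_new - H;
        if (dH <= 0.0 || R::runif(0.0, 1.0) < std::exp(-dH)) {
          if (is_resid) sigma_resid = prop;
          else { sigma_acc(j) = prop; s2_obs = s2_new; }
          st = st_new; H = H_new; ++nas;
        }
      }
    }
    h_trace(s) = H;
    acc_beta_trace(s) = nab; acc_sigma_trace(s) = nas;
    att_beta_trace(s) = attb; att_sigma_trace(s) = atts;
  }
  return List::create(_["beta"] = beta, _["sigma_acc"] = sigma_acc,
                      _["sigma_resid"] = sigma_resid, _["H"] = H,
                      _["h_trace"] = h_trace,
                      _["acc_beta"] = acc_beta_trace,
                      _["acc_sigma"] = acc_sigma_trace,
                      _["att_beta"] = att_beta_trace,
                      _["att_sigma"] = att_sigma_trace);
}
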