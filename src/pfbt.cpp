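#include <Rcpp.h>
using namespace Rcpp;

// Beta shapes with a given interior mode m and variance v, constrained to
// a, b >= 1 so the mode is interior and unique. Parametrise a = 1 + m*k,
// b = 1 + (1-m)*k with k >= 0: the mode is m for every k, and the variance
// decreases monotonically from 1/12 (k = 0, the uniform) towards 0, so any
// v in (0, 1/12) has a unique solution found by bisection on k.
static inline double beta_var_at_k(double m, double k) {
  double a = 1.0 + m * k;
  double b = 1.0 + (1.0 - m) * k;
  double s = a + b;
  return a * b / (s * s * (s + 1.0));
}

static void solve_beta_shapes(double mode, double variance,
                              double &a, double &b, bool &shrunk) {
  const double vmax = 1.0 / 12.0 - 1e-9;
  shrunk = false;
  if (variance >= vmax) {  // infeasible for a,b >= 1: shrink to the feasible max
    variance = vmax;
    shrunk = true;
  }
  double lo = 0.0, hi = 1.0;
  while (beta_var_at_k(mode, hi) > variance) hi *= 2.0;
  for (int i = 0; i < 100; ++i) {
    double mid = 0.5 * (lo + hi);
    if (beta_var_at_k(mode, mid) > variance) lo = mid; else hi = mid;
  }
  double k = 0.5 * (lo + hi);
  a = 1.0 + mode * k;
  b = 1.0 + (1.0 - mode) * k;
}

// [[Rcpp::export]]
List cpp_beta_shapes(NumericVector mode, NumericVector variance) {
  int n = mode.size();
  NumericVector a(n), b(n);
  LogicalVector shrunk(n);
  for (int i = 0; i < n; ++i) {
    double ai, bi;
    bool sh;
    solve_beta_shapes(mode[i], variance[i], ai, bi, sh);
    a[i] = ai; b[i] = bi; shrunk[i] = sh;
  }
  return List::create(_["shape1"] = a, _["shape2"] = b, _["shrunk"] = shrunk);
}

// Dual-agent belief recursion. Trial-type codes: 0 shared, 1 privileged,
// 2 decoy. PE^Self is zeroed on decoy trials, PE^Other on privileged trials;
// both beliefs decay towards 0.5 on every sampling trial and are clipped to
// [0,1] after each update.
// [[Rcpp::export]]
NumericMatrix cpp_trajectory(IntegerVector outcome, IntegerVector type,
                             double alpha_self, double alpha_other,
                             double delta, double lambda_self,
                             double lambda_other, double b_self0,
                             double b_other0) {
  int n = outcome.size();
  NumericMatrix out(n, 4);
  double bs = b_self0, bo = b_other0;
  for (int t = 0; t < n; ++t) {
    double pes = (type[t] == 2) ? 0.0 : outcome[t] - bs;
    double peo = (type[t] == 1) ? 0.0 : outcome[t] - bo;
    double nbs = bs + alpha_self * (pes + lambda_other * peo) + delta * (0.5 - bs);
    double nbo = bo + alpha_other * (peo + lambda_self * pes) + delta * (0.5 - bo);
    bs = std::min(1.0, std::max(0.0, nbs));
    bo = std::min(1.0, std::max(0.0, nbo));
    out(t, 0) = bs;
    out(t, 1) = bo;
    out(t, 2) = pes;
    out(t, 3) = peo;
  }
  return out;
}

// Summed log Beta density of probe responses. probe_after holds the 1-based
// index of the sampling trial preceding each probe (0 = before any sampling
// trial); probe_agent is 0 for Self, 1 for Other. Modes and responses are
// clamped into [eps, 1-eps].
// [[Rcpp::export]]
double cpp_response_loglik(IntegerVector outcome, IntegerVector type,
                           IntegerVector probe_after, IntegerVector probe_agent,
                           NumericVector response, double alpha_self,
                           double alpha_other, double delta,
                           double lambda_self, double lambda_other, double tau,
                           double b_self0, double b_other0, double eps) {
  int n = outcome.size();
  std::vector<double> BS(n), BO(n);
  double bs = b_self0, bo = b_other0;
  for (int t = 0; t < n; ++t) {
    double pes = (type[t] == 2) ? 0.0 : outcome[t] - bs;
    double peo = (type[t] == 1) ? 0.0 : outcome[t] - bo;
    double nbs = bs + alpha_self * (pes + lambda_other * peo) + delta * (0.5 - bs);
    double nbo = bo + alpha_other * (peo + lambda_self * pes) + delta * (0.5 - bo);
    bs = std::min(1.0, std::max(0.0, nbs));
    bo = std::min(1.0, std::max(0.0, nbo));
    BS[t] = bs;
    BO[t] = bo;
  }
  int np = probe_after.size();
  double ll = 0.0;
  for (int i = 0; i < np; ++i) {
    int idx = probe_after[i];
    double m = (probe_agent[i] == 0)
      ? (idx > 0 ? BS[idx - 1] : b_self0)
      : (idx > 0 ? BO[idx - 1] : b_other0);
    if (m < eps) m = eps;
    if (m > 1.0 - eps) m = 1.0 - eps;
    double a, b;
    bool sh;
    solve_beta_shapes(m, tau, a, b, sh);
    double x = response[i];
    if (x < eps) x = eps;
    if (x > 1.0 - eps) x = 1.0 - eps;
    ll += R::dbeta(x, a, b, 1);
  }
  return ll;
}
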