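// FRAPPE-style EM inner loop for the binomial admixture likelihood.
// g / cg are the derived / ancestral copy counts with missing entries
// already zeroed (so they drop out of every sum).  Explicit fused loops:
// the E-step, M-step accumulators and log-likelihood share one pass over
// the n x m genotype table, with cluster-major access (Qt is k x n, P is
// k x m, both column-contiguous).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-9;

static inline double clampp(double x) {
  return x < EPS ? EPS : (x > 1.0 - EPS ? 1.0 - EPS : x);
}

// log-likelihood at (Qt, P)
static double ll_pass(const mat& g, const mat& cg, const mat& Qt,
                      const mat& P) {
  const uword n = g.n_rows, m = g.n_cols, k = Qt.n_rows;
  double ll = 0.0;
  for (uword s = 0; s < m; ++s) {
    const double* pc = P.colptr(s);
    const double* gc = g.colptr(s);
    const double* cgc = cg.colptr(s);
    for (uword i = 0; i < n; ++i) {
      const double* qc = Qt.colptr(i);
      double f = 0.0;
      for (uword j = 0; j < k; ++j) f += qc[j] * pc[j];
      f = clampp(f);
      ll += gc[i] * std::log(f) + cgc[i] * std::log(1.0 - f);
    }
  }
  return ll;
}

// [[Rcpp::export(name = ".admix_em_cpp")]]
Rcpp::List admix_em_cpp(const arma::mat& g, const arma::mat& cg,
                        arma::mat Q, arma::mat P, double tol, int max_iter,
                        bool update_p) {
  const uword n = g.n_rows, m = g.n_cols, k = Q.n_cols;
  mat Qt = Q.t();                       // k x n
  std::vector<double> trace;
  bool converged = false, decreased = false;
  // the per-iteration log-likelihood is evaluated inside the E-step pass
  // at the parameters *entering* the iteration, so each iteration costs
  // one pass; the EM guarantee (non-decreasing sequence) applies to this
  // sequence exactly
  double ll = -datum::inf;
  int iter = 0;
  mat q_acc(k, n), p_num(k, m), p_den(k, m);
  while (iter < max_iter) {
    ++iter;
    q_acc.zeros();
    if (update_p) { p_num.zeros(); p_den.zeros(); }
    double ll_cur = 0.0;
    for (uword s = 0; s < m; ++s) {
      const double* pc = P.colptr(s);
      const double* gc = g.colptr(s);
      const double* cgc = cg.colptr(s);
      double* pn = update_p ? p_num.colptr(s) : nullptr;
      double* pd = update_p ? p_den.colptr(s) : nullptr;
      for (uword i = 0; i < n; ++i) {
        const double gi = gc[i], cgi = cgc[i];
        if (gi == 0.0 && cgi == 0.0) continue;   // missing genotype
        const double* qc = Qt.colptr(i);
        double* qa = q_acc.colptr(i);
        double f = 0.0;
        for (uword j = 0; j < k; ++j) f += qc[j] * pc[j];
        f = clampp(f);
        ll_cur += gi * std::log(f) + cgi * std::log(1.0 - f);
        const double ga = gi / f, gb = cgi / (1.0 - f);
        for (uword j = 0; j < k; ++j) {
          const double a = qc[j] * pc[j] * ga;          // derived from j
          const double b = qc[j] * (1.0 - pc[j]) * gb;  // ancestral from j
          qa[j] += a + b;
          if (update_p) { pn[j] += a; pd[j] += a + b; }
        }
      }
    }
    trace.push_back(ll_cur);
    if (iter > 1) {
      if (ll_cur < ll - 1e-8 * std::max(1.0, std::fabs(ll))) {
        decreased = true;
        ll = ll_cur;
        break;
      }
      if (std::fabs(ll_cur - ll) < tol * std::max(1.0, std::fabs(ll))) {
        ll = ll_cur;
        converged = true;
        break;
      }
    }
    ll = ll_cur;
    // M-step: Q rows renormalized onto the simplex (clamped), P = ratio
    for (uword i = 0; i < n; ++i) {
      double* qa = q_acc.colptr(i);
      double tot = 0.0;
      for (uword j = 0; j < k; ++j) tot += qa[j];
      double tot2 = 0.0;
      for (uword j = 0; j < k; ++j) {
        qa[j] = tot > 0 ? qa[j] / tot : 1.0 / k;
        if (qa[j] < EPS) qa[j] = EPS;
        tot2 += qa[j];
      }
      for (uword j = 0; j < k; ++j) Qt(j, i) = qa[j] / tot2;
    }
    if (update_p) {
      for (uword s = 0; s < m; ++s) {
        for (uword j = 0; j < k; ++j) {
          double den = p_den(j, s);
          // no information for this cluster at this site: keep frequency
          P(j, s) = den < EPS ? P(j, s) : clampp(p_num(j, s) / den);
        }
      }
    }
  }
  if (!converged && !decreased) {
    // max_iter exhausted after an M-step: evaluate the final parameters
    ll = ll_pass(g, cg, Qt, P);
    trace.push_back(ll);
  }
  return Rcpp::List::create(
      Rcpp::Named("Q") = Qt.t(), Rcpp::Named("P") = P,
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("decreased") = decreased);
}
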