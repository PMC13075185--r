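#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the elastic net in moment space.
// gram is the standardized Gram matrix X'X/n (diagonal == 1), xty = X'y/n,
// yty = y'y/n. Objective: rss/2n + lambda*(alpha*||b||_1 + (1-alpha)/2*||b||_2^2).
// [[Rcpp::export(name = ".enet_solve_cpp")]]
List enet_solve_cpp(NumericMatrix gram, NumericVector xty, double yty,
                    double lambda, double alpha, NumericVector beta_init,
                    double tol, int max_sweeps, bool trace) {
  const int p = xty.size();
  NumericVector beta = clone(beta_init);
  NumericVector grad(p);  // gram %*% beta, maintained incrementally
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      for (int i = 0; i < p; ++i) grad[i] += gram(i, j) * beta[j];
    }
  }
  const double denom = 1.0 + lambda * (1.0 - alpha);
  const double thr = lambda * alpha;
  std::vector<double> obj;
  bool converged = false;
  int sweeps = 0;
  while (sweeps < max_sweeps) {
    ++sweeps;
    double max_delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double bj = beta[j];
      const double z = xty[j] - grad[j] + bj;
      double bn = 0.0;
      if (z > thr) bn = (z - thr) / denom;
      else if (z < -thr) bn = (z + thr) / denom;
      if (bn != bj) {
        const double d = bn - bj;
        for (int i = 0; i < p; ++i) grad[i] += gram(i, j) * d;
        beta[j] = bn;
        const double ad = d < 0 ? -d : d;
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (trace) {
      double rss_n = yty;
      double l1 = 0.0, l2 = 0.0;
      for (int j = 0; j < p; ++j) {
        rss_n += beta[j] * (grad[j] - 2.0 * xty[j]);
        l1 += beta[j] < 0 ? -beta[j] : beta[j];
        l2 += beta[j] * beta[j];
      }
      obj.push_back(rss_n / 2.0 + lambda * (alpha * l1 + (1 - alpha) * l2 / 2.0));
    }
    if (max_delta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["obj_trace"] = trace ? wrap(obj) : R_NilValue);
}
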