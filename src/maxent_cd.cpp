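#include <Rcpp.h>
using namespace Rcpp;

// L1-penalized presence-background maximum-entropy fit by cyclic
// coordinate descent with soft-thresholding and step-halving.
// Objective: -sum_j fbar_j lambda_j + log sum_bg exp(eta) + sum_j beta_j |lambda_j|
// where eta = F_bg lambda and fbar are presence feature means.

static double log_sum_exp(const std::vector<double>& eta) {
  double m = eta[0];
  for (size_t i = 1; i < eta.size(); ++i) if (eta[i] > m) m = eta[i];
  double s = 0.0;
  for (size_t i = 0; i < eta.size(); ++i) s += std::exp(eta[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export(name = ".maxent_cd")]]
List maxent_cd(NumericMatrix Fbg, NumericVector fbar, NumericVector beta,
               int max_iter, double tol) {
  const int n = Fbg.nrow(), p = Fbg.ncol();
  std::vector<double> eta(n, 0.0), q(n), lambda(p, 0.0), feat_gain(p, 0.0);
  double logZ = std::log((double) n);
  auto objective = [&](const std::vector<double>& et,
                       const std::vector<double>& lam) {
    double lin = 0.0, pen = 0.0;
    for (int j = 0; j < p; ++j) {
      lin += fbar[j] * lam[j];
      pen += beta[j] * std::fabs(lam[j]);
    }
    return -lin + log_sum_exp(et) + pen;
  };
  double obj = objective(eta, lambda);
  bool converged = false;
  int cycles = 0;
  std::vector<double> eta_try(n), lam_try(p);
  for (int iter = 0; iter < max_iter; ++iter) {
    ++cycles;
    double obj_start = obj;
    // refresh q from eta
    double m = eta[0];
    for (int i = 1; i < n; ++i) if (eta[i] > m) m = eta[i];
    double Z = 0.0;
    for (int i = 0; i < n; ++i) { q[i] = std::exp(eta[i] - m); Z += q[i]; }
    for (int i = 0; i < n; ++i) q[i] /= Z;
    for (int j = 0; j < p; ++j) {
      const double* fj = &Fbg(0, j);
      double Eq = 0.0, Eq2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double qf = q[i] * fj[i];
        Eq += qf;
        Eq2 += qf * fj[i];
      }
      double g = Eq - fbar[j];
      double h = Eq2 - Eq * Eq;
      if (h < 1e-10) h = 1e-10;
      double zraw = h * lambda[j] - g;
      double lam_new = 0.0;
      if (zraw > beta[j]) lam_new = (zraw - beta[j]) / h;
      else if (zraw < -beta[j]) lam_new = (zraw + beta[j]) / h;
      double delta = lam_new - lambda[j];
      if (std::fabs(delta) < 1e-12) continue;
      if (delta > 2.0) delta = 2.0;
      if (delta < -2.0) delta = -2.0;
      for (int half = 0; half <= 12; ++half) {
        double d = delta / (double)(1 << half);
        for (int i = 0; i < n; ++i) eta_try[i] = eta[i] + d * fj[i];
        lam_try = lambda;
        lam_try[j] += d;
        double obj_try = objective(eta_try, lam_try);
        if (obj_try <= obj + 1e-12) {
          if (obj - obj_try > 0) feat_gain[j] += obj - obj_try;
          eta.swap(eta_try);
          lambda[j] += d;
          obj = obj_try;
          // refresh q
          double mm = eta[0];
          for (int i = 1; i < n; ++i) if (eta[i] > mm) mm = eta[i];
          double ZZ = 0.0;
          for (int i = 0; i < n; ++i) { q[i] = std::exp(eta[i] - mm); ZZ += q[i]; }
          for (int i = 0; i < n; ++i) q[i] /= ZZ;
          break;
        }
      }
    }
    if (obj_start - obj < tol) { converged = true; break; }
  }
  logZ = log_sum_exp(eta);
  return List::create(_["lambda"] = NumericVector(lambda.begin(), lambda.end()),
                      _["feat_gain"] = NumericVector(feat_gain.begin(), feat_gain.end()),
                      _["objective"] = obj,
                      _["log_partition"] = logZ,
                      _["converged"] = converged,
                      _["cycles"] = cycles);
}
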