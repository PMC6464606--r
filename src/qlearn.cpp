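#include <Rcpp.h>
using namespace Rcpp;

// Forward pass of the Q recursion with a stay bonus.
// choice: 1 = contra, 0 = ipsi; reset marks trials where Q and the stay
// indicator are re-initialised (start of a subject's concatenated record,
// or of a session when per-session resetting is requested).
static double nll_one(double alpha, double beta, double stay,
                      const int* choice, const int* reward, const int* reset,
                      int n) {
  double qc = 0.0, qi = 0.0, nll = 0.0;
  int prev = -1;
  for (int t = 0; t < n; ++t) {
    if (reset[t]) { qc = 0.0; qi = 0.0; prev = -1; }
    double x = beta * (qc - qi);
    if (prev == 1) x += stay;
    else if (prev == 0) x -= stay;
    double p = 1.0 / (1.0 + std::exp(-x));
    double pc = (choice[t] == 1) ? p : 1.0 - p;
    if (pc < 1e-300) pc = 1e-300;
    nll -= std::log(pc);
    if (choice[t] == 1) qc += alpha * (reward[t] - qc);
    else                qi += alpha * (reward[t] - qi);
    prev = choice[t];
  }
  return nll;
}

//' @noRd
// [[Rcpp::export(name = ".nll_qlearn_cpp")]]
double nll_qlearn_cpp(double alpha, double beta, double stay,
                      IntegerVector choice, IntegerVector reward,
                      IntegerVector reset) {
  return nll_one(alpha, beta, stay, INTEGER(choice), INTEGER(reward),
                 INTEGER(reset), choice.size());
}

// Per-subject negative log-likelihoods for a concatenated multi-subject
// record. start is 0-based offset of each subject's first trial.
// [[Rcpp::export(name = ".nll_qlearn_multi_cpp")]]
NumericVector nll_qlearn_multi_cpp(NumericVector alpha, NumericVector beta,
                                   NumericVector stay, IntegerVector choice,
                                   IntegerVector reward, IntegerVector reset,
                                   IntegerVector start, IntegerVector len) {
  int J = start.size();
  NumericVector out(J);
  for (int j = 0; j < J; ++j) {
    out[j] = nll_one(alpha[j], beta[j], stay[j],
                     INTEGER(choice) + start[j], INTEGER(reward) + start[j],
                     INTEGER(reset) + start[j], len[j]);
  }
  return out;
}

// Q values at decision time (before the trial's update), both actions.
// [[Rcpp::export(name = ".qpath_cpp")]]
NumericMatrix qpath_cpp(double alpha, IntegerVector choice,
                        IntegerVector reward, IntegerVector reset) {
  int n = choice.size();
  NumericMatrix out(n, 2);
  double qc = 0.0, qi = 0.0;
  for (int t = 0; t < n; ++t) {
    if (reset[t]) { qc = 0.0; qi = 0.0; }
    out(t, 0) = qc;
    out(t, 1) = qi;
    if (choice[t] == 1) qc += alpha * (reward[t] - qc);
    else                qi += alpha * (reward[t] - qi);
  }
  return out;
}

// Unconstrained -> natural scale: th = (logit alpha, log beta, stay)
static inline double tr_alpha(double a) { return 1.0 / (1.0 + std::exp(-a)); }
static inline double tr_beta(double b)  { return std::exp(b); }

// Log joint of one subject's block: likelihood at natural-scale params plus
// the Gaussian group prior on the unconstrained scale.
static double subj_lp(const double* th, const double* mu, const double* sigma,
                      const int* choice, const int* reward, const int* reset,
                      int n) {
  if (std::fabs(th[0]) > 30.0 || std::fabs(th[1]) > 30.0 ||
      std::fabs(th[2]) > 30.0)
    return R_NegInf;
  double lp = -nll_one(tr_alpha(th[0]), tr_beta(th[1]), th[2],
                       choice, reward, reset, n);
  for (int k = 0; k < 3; ++k)
    lp += R::dnorm(th[k], mu[k], sigma[k], 1);
  return lp;
}

// One slice-sampling scan (stepping-out + shrinkage, Neal 2003) over all
// subjects. theta is J x 3 on the unconstrained scale. Each subject is
// updated along three direction vectors (columns of its 3x3 block of rot,
// column-major, J blocks) with per-direction initial widths (J x 3); the
// identity with unit widths gives plain component-wise slice sampling.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".slice_scan_cpp")]]
NumericMatrix slice_scan_cpp(NumericMatrix theta, NumericVector mu,
                             NumericVector sigma, IntegerVector choice,
                             IntegerVector reward, IntegerVector reset,
                             IntegerVector start, IntegerVector len,
                             NumericVector rot, NumericMatrix widths,
                             int max_step) {
  int J = theta.nrow();
  NumericMatrix th = clone(theta);
  for (int j = 0; j < J; ++j) {
    const int* ch = INTEGER(choice) + start[j];
    const int* rw = INTEGER(reward) + start[j];
    const int* rs = INTEGER(reset) + start[j];
    const double* Rj = REAL(rot) + 9 * j;
    int n = len[j];
    double cur[3] = { th(j, 0), th(j, 1), th(j, 2) };
    double lp0 = subj_lp(cur, REAL(mu), REAL(sigma), ch, rw, rs, n);
    double prop[3];
    for (int k = 0; k < 3; ++k) {
      const double* dir = Rj + 3 * k;
      double w = widths(j, k);
      double logy = lp0 - R::exp_rand();
      double u = R::unif_rand();
      double L = -w * u;        // slice in t around t = 0
      double Rr = L + w;
      int m = max_step;
      int jcnt = (int)std::floor(R::unif_rand() * m);
      int kcnt = m - 1 - jcnt;
      double lpL, lpR;
      while (jcnt > 0) {
        for (int d = 0; d < 3; ++d) prop[d] = cur[d] + L * dir[d];
        lpL = subj_lp(prop, REAL(mu), REAL(sigma), ch, rw, rs, n);
        if (lpL <= logy) break;
        L -= w; --jcnt;
      }
      while (kcnt > 0) {
        for (int d = 0; d < 3; ++d) prop[d] = cur[d] + Rr * dir[d];
        lpR = subj_lp(prop, REAL(mu), REAL(sigma), ch, rw, rs, n);
        if (lpR <= logy) break;
        Rr += w; --kcnt;
      }
      double t1, lp1;
      for (;;) {
        t1 = L + R::unif_rand() * (Rr - L);
        for (int d = 0; d < 3; ++d) prop[d] = cur[d] + t1 * dir[d];
        lp1 = subj_lp(prop, REAL(mu), REAL(sigma), ch, rw, rs, n);
        if (lp1 > logy) break;
        if (t1 < 0) L = t1; else Rr = t1;
        if (Rr - L < 1e-12) {
          t1 = 0; lp1 = lp0;
          for (int d = 0; d < 3; ++d) prop[d] = cur[d];
          break;
        }
      }
      for (int d = 0; d < 3; ++d) cur[d] = prop[d];
      lp0 = lp1;
    }
    for (int d = 0; d < 3; ++d) th(j, d) = cur[d];
  }
  return th;
}
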