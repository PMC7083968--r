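#include <Rcpp.h>
using namespace Rcpp;

// Shared BRAID surface evaluation on the natural parameter scale.
// p = (idmA, idmB, na, nb, kappa, e0, efA, efB).  Spans straddling e0 are
// clamped (the smaller offender is pulled to e0), matching the R fitting
// guard.
static inline void braid_eval(const double *p, const double *dA,
                              const double *dB, double *out, int n) {
  double idmA = p[0], idmB = p[1], na = p[2], nb = p[3], kappa = p[4];
  double e0 = p[5], efA = p[6], efB = p[7];
  double sA = efA - e0, sB = efB - e0;
  if (sA * sB < 0) {
    if (std::fabs(sA) < std::fabs(sB)) sA = 0.0; else sB = 0.0;
  }
  double spanf = (std::fabs(sA) >= std::fabs(sB)) ? sA : sB;
  if (spanf == 0.0) {
    for (int i = 0; i < n; i++) out[i] = e0;
    return;
  }
  double FA = sA / spanf, FB = sB / spanf;
  double h = std::sqrt(na * nb), ih = 1.0 / h;
  for (int i = 0; i < n; i++) {
    double xA = std::pow(dA[i] / idmA, na);
    double xB = std::pow(dB[i] / idmB, nb);
    double tA, tB;
    if (!R_finite(xA))
      tA = (FA < 1.0) ? std::pow(FA / (1.0 - FA), ih) : R_PosInf;
    else
      tA = std::pow(FA * xA / (1.0 + (1.0 - FA) * xA), ih);
    if (!R_finite(xB))
      tB = (FB < 1.0) ? std::pow(FB / (1.0 - FB), ih) : R_PosInf;
    else
      tB = std::pow(FB * xB / (1.0 + (1.0 - FB) * xB), ih);
    double frac;
    if (!R_finite(tA) || !R_finite(tB)) {
      frac = 1.0;
    } else {
      double cross = (tA > 0.0 && tB > 0.0) ? kappa * std::sqrt(tA * tB) : 0.0;
      double D = tA + tB + cross;
      if (D <= 0.0) {
        frac = 0.0;
      } else {
        double Dh = std::pow(D, h);
        frac = R_finite(Dh) ? Dh / (1.0 + Dh) : 1.0;
      }
    }
    out[i] = e0 + spanf * frac;
  }
}

static inline void th_to_natural(const NumericVector &th, double *p) {
  p[0] = std::exp(th[0]);
  p[1] = std::exp(th[1]);
  p[2] = std::exp(th[2]);
  p[3] = std::exp(th[3]);
  p[4] = std::exp(th[4]) - 2.0;
  p[5] = th[5];
  p[6] = th[6];
  p[7] = th[7];
}

// [[Rcpp::export]]
NumericVector braid_eval_cpp(NumericVector params, NumericVector dA,
                             NumericVector dB) {
  int n = dA.size();
  NumericVector out(n);
  braid_eval(params.begin(), dA.begin(), dB.begin(), out.begin(), n);
  return out;
}

// Residuals (model - y) on the transformed parameter scale used by the
// least-squares optimiser: (log idmA, log idmB, log na, log nb,
// log(kappa + 2), e0, efA, efB).
// [[Rcpp::export]]
NumericVector braid_resid_cpp(NumericVector th, NumericVector dA,
                              NumericVector dB, NumericVector y) {
  int n = dA.size();
  double p[8];
  th_to_natural(th, p);
  NumericVector out(n);
  braid_eval(p, dA.begin(), dB.begin(), out.begin(), n);
  for (int i = 0; i < n; i++) out[i] -= y[i];
  return out;
}

// Negative Poisson log-likelihood of colony counts under a BRAID
// log-plating-efficiency surface, on the transformed parameter scale.
// [[Rcpp::export]]
double braid_poisson_negll_cpp(NumericVector th, NumericVector dA,
                               NumericVector dB, NumericVector counts,
                               double density) {
  int n = dA.size();
  double p[8];
  th_to_natural(th, p);
  NumericVector eta(n);
  braid_eval(p, dA.begin(), dB.begin(), eta.begin(), n);
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double mu = density * std::exp(eta[i]);
    if (mu < 1e-12) mu = 1e-12;
    ll += R::dpois(counts[i], mu, 1);
  }
  return -ll;
}
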