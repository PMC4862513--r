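#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Depot -> central -> peripheral system with a time-varying absorption rate
// constant ka(t) = kamax * (1 - exp(-(ra*t)^gam1)). States are amounts (ng):
// y0 depot, y1 central, y2 peripheral. Explicit Dormand-Prince RK5(4) with
// adaptive step control; the system is non-stiff (rate constants are O(1)/h).

struct Pars {
  double ke, k12, k21, ra, gam1, kamax;
};

static inline void deriv(double t, const double* y, double* dy, const Pars& p) {
  double ka = 0.0;
  if (t > 0.0) {
    double x = std::pow(p.ra * t, p.gam1);
    // for large x, 1 - exp(-x) == 1 exactly
    ka = p.kamax * (x > 36.0 ? 1.0 : -std::expm1(-x));
  }
  dy[0] = -ka * y[0];
  dy[1] = ka * y[0] - (p.ke + p.k12) * y[1] + p.k21 * y[2];
  dy[2] = p.k12 * y[1] - p.k21 * y[2];
}

// Dormand-Prince coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// [[Rcpp::export]]
NumericVector oral_weibull_central(NumericVector times, double dose_ng,
                                   double cl, double vc, double q, double vp,
                                   double ra, double gam1, double kamax,
                                   double f1, double rtol = 1e-10,
                                   double atol_frac = 1e-12) {
  const int n = times.size();
  NumericVector out(n);
  if (dose_ng <= 0.0) return out;

  Pars p;
  p.ke = cl / vc;
  p.k12 = q / vc;
  p.k21 = q / vp;
  p.ra = ra;
  p.gam1 = gam1;
  p.kamax = kamax;

  double y[3] = {dose_ng * f1, 0.0, 0.0};
  const double atol = atol_frac * dose_ng;
  double t = 0.0;
  double h = 1e-3;
  const double hmin = 1e-12;
  long max_steps = 5000000;

  double k1[3], k2[3], k3[3], k4[3], k5[3], k6[3], k7[3], ytmp[3], ynew[3];
  bool have_k1 = false;

  for (int i = 0; i < n; ++i) {
    double tout = times[i];
    if (tout < 0.0) stop("numerical error: negative output time");
    if (tout <= t + 1e-14) {
      out[i] = y[1] / vc;
      continue;
    }
    while (t < tout - 1e-12) {
      if (--max_steps < 0)
        stop("numerical error: oral absorption integration exceeded step budget");
      double hs = h;
      bool hit = false;
      if (t + hs >= tout) { hs = tout - t; hit = true; }
      if (!have_k1) deriv(t, y, k1, p);
      for (int j = 0; j < 3; ++j) ytmp[j] = y[j] + hs * a21 * k1[j];
      deriv(t + c2 * hs, ytmp, k2, p);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (a31 * k1[j] + a32 * k2[j]);
      deriv(t + c3 * hs, ytmp, k3, p);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      deriv(t + c4 * hs, ytmp, k4, p);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                               a54 * k4[j]);
      deriv(t + c5 * hs, ytmp, k5, p);
      for (int j = 0; j < 3; ++j)
        ytmp[j] = y[j] + hs * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                               a64 * k4[j] + a65 * k5[j]);
      deriv(t + hs, ytmp, k6, p);
      for (int j = 0; j < 3; ++j)
        ynew[j] = y[j] + hs * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                               b5 * k5[j] + b6 * k6[j]);
      deriv(t + hs, ynew, k7, p);

      double err = 0.0;
      for (int j = 0; j < 3; ++j) {
        double y4 = y[j] + hs * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                                 e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        double e = std::fabs(ynew[j] - y4) / sc;
        if (e > err) err = e;
      }
      if (err <= 1.0) {
        t += hs;
        for (int j = 0; j < 3; ++j) { y[j] = ynew[j]; k1[j] = k7[j]; }
        have_k1 = true;  // FSAL
        double fac = (err <= 0.0) ? 5.0 : 0.9 * std::pow(err, -0.2);
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        if (!hit) h = hs * fac; else if (fac > 1.0) h = h * fac;
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        if (fac < 0.1) fac = 0.1;
        h = hs * fac;
        have_k1 = false;
        if (h < hmin)
          stop("numerical error: step size underflow in oral absorption solver");
      }
    }
    out[i] = y[1] / vc;
  }
  return out;
}
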