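#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fused simulation cores for the estimation hot loop. These mirror the R
// reference implementation (see R/dilv-model.R) term for term; the R path
// remains the source of component traces and the two are cross-checked in
// the test suite. A degenerate normalization is signalled by returning a
// zero-length vector, which the R wrapper raises as a classed condition.


// Squashed sinusoidal drive computed with a rotation recurrence for the
// sine (exact to ~1e-12 over these window lengths) and a saturation
// shortcut for the tanh (|x| > 19 is 1 ulp from the limit).
static void squashed_drive(std::vector<double>& out, long N, long n_burn,
                           double w, double dt, double t_start,
                           double phi, double b, double a) {
  const double ang0 = w * (t_start - (double)n_burn * dt) - phi;
  double s = std::sin(ang0), c = std::cos(ang0);
  const double sd = std::sin(w * dt), cd = std::cos(w * dt);
  for (long i = 0; i < N; ++i) {
    double x = a * (s - b);
    if (x > 19.0) out[i] = 1.0;
    else if (x < -19.0) out[i] = 0.0;
    else out[i] = 0.5 * (std::tanh(x) + 1.0);
    double s2 = s * cd + c * sd;
    c = c * cd - s * sd;
    s = s2;
  }
}

static inline long burn_samples(double burn_in_periods, double period_samples,
                                double tau) {
  long a = (long)std::ceil(burn_in_periods * period_samples);
  long b = (long)std::ceil(8.0 * tau);
  return std::max(a, b);
}

static inline double tau_leak_cpp(double beta) {
  if (beta <= 1.0 + 1e-9) return 0.0;
  return std::min(1.0 / std::log(beta), 2500.0);
}

// [[Rcpp::export]]
NumericVector sim_volume_cpp(double theta, double a1, double b1, double phi1,
                             double beta1, double beta2, double Av,
                             double dt, int n, double t_start,
                             double burn_in_periods, bool corrected) {
  const double period_samples = 1.0 / (theta * dt);
  const long n_burn = burn_samples(burn_in_periods, period_samples,
                                   std::max(beta1, beta2));
  const long n_win = std::max((long)n, (long)std::ceil(period_samples));
  const long N = n_burn + n_win;
  std::vector<double> fb1(N), fv1(N), fv2(N);
  const double w = 2.0 * M_PI * theta;
  squashed_drive(fb1, N, n_burn, w, dt, t_start, phi1, b1, a1);
  const double c1 = 1.0 / beta1, r1 = 1.0 - c1;
  const double c2 = 1.0 / beta2, r2 = 1.0 - c2;
  fv1[0] = 0.0; fv2[0] = 0.0;
  for (long i = 1; i < N; ++i) {
    fv1[i] = c1 * fb1[i] + r1 * fv1[i - 1];
    fv2[i] = c2 * fb1[i] + r2 * fv2[i - 1];
  }
  double m1 = R_NegInf, m2 = R_NegInf;
  for (long i = n_burn; i < N; ++i) {
    m1 = std::max(m1, fv1[i]);
    m2 = std::max(m2, fv2[i]);
  }
  if (!(m1 > 1e-9) || !(m2 > 1e-9)) return NumericVector(0);
  NumericVector V(n);
  for (int i = 0; i < n; ++i) {
    long j = n_burn + i;
    double mask2 = corrected ? 1.0 - fb1[j] : fb1[j];
    V[i] = Av * (fv1[j] * fb1[j] / m1 + fv2[j] * mask2 / m2);
  }
  return V;
}

// [[Rcpp::export]]
NumericVector sim_pressure_cpp(double theta, double a2, double b2, double phi2,
                               double a3, double b3, double phi3,
                               double beta3, double beta4, double beta5,
                               double beta6, double Ap1, double Ap2,
                               double Ap3, double Ap4,
                               double dt, int n, double t_start,
                               double burn_in_periods, bool corrected) {
  const double period_samples = 1.0 / (theta * dt);
  double tau = std::max(beta3, beta4);
  if (Ap2 > 0.0) {
    tau = std::max(tau, std::max(tau_leak_cpp(beta5), tau_leak_cpp(beta6)));
  }
  const long n_burn = burn_samples(burn_in_periods, period_samples, tau);
  const long n_win = std::max((long)n, (long)std::ceil(period_samples));
  const long N = n_burn + n_win;
  std::vector<double> fb2(N), fp11(N), fp12(N);
  const double w = 2.0 * M_PI * theta;
  squashed_drive(fb2, N, n_burn, w, dt, t_start, phi2, b2, a2);
  const double c3 = 1.0 / beta3, r3 = 1.0 - c3;
  const double c4 = 1.0 / beta4, r4 = 1.0 - c4;
  fp11[0] = 0.0; fp12[0] = 0.0;
  for (long i = 1; i < N; ++i) {
    fp11[i] = c3 * fb2[i] + r3 * fp11[i - 1];
    fp12[i] = c4 * fb2[i] + r4 * fp12[i - 1];
  }
  double m11 = R_NegInf, m12 = R_NegInf;
  for (long i = n_burn; i < N; ++i) {
    m11 = std::max(m11, fp11[i]);
    m12 = std::max(m12, fp12[i]);
  }
  if (!(m11 > 1e-9) || !(m12 > 1e-9)) return NumericVector(0);

  // plateau-peak component: leaky differencing of the drive, masked,
  // differenced again and rectified
  std::vector<double> fp23;
  double m23 = 0.0;
  if (Ap2 > 0.0) {
    std::vector<double> fp21(N), fp22(N);
    const double c5 = 1.0 / beta5, c6 = 1.0 / beta6;
    fp21[0] = 0.0;
    for (long i = 1; i < N; ++i) {
      fp21[i] = c5 * (fp21[i - 1] + fb2[i] - fb2[i - 1]);
    }
    for (long i = 0; i < N; ++i) fp22[i] = fp21[i] * fb2[i];
    fp23.resize(N);
    fp23[0] = 0.0;
    for (long i = 1; i < N; ++i) {
      fp23[i] = c6 * (fp23[i - 1] + fp22[i] - fp22[i - 1]);
    }
    for (long i = 0; i < N; ++i) fp23[i] = std::fabs(fp23[i]);
    for (long i = n_burn; i < N; ++i) m23 = std::max(m23, fp23[i]);
    if (!(m23 > 1e-9)) return NumericVector(0);
  }

  // low-volume knee: short pulse confined to the window where the main
  // component is small
  std::vector<double> g;
  double mg = 0.0;
  if (Ap3 > 0.0) {
    g.resize(n_win);
    std::vector<double> fp32v(n_win);
    squashed_drive(fp32v, n_win, 0, w, dt, t_start, phi3, b3, a3);
    for (long i = n_burn; i < N; ++i) {
      double fp32 = fp32v[i - n_burn];
      double mask12 = corrected ? 1.0 - fb2[i] : fb2[i];
      double lowwin = 1.0 - (fp11[i] * fb2[i] / m11 + fp12[i] * mask12 / m12);
      g[i - n_burn] = fp32 * lowwin;
      mg = std::max(mg, g[i - n_burn]);
    }
    if (!(mg > 1e-9)) return NumericVector(0);
  }

  NumericVector P(n);
  for (int i = 0; i < n; ++i) {
    long j = n_burn + i;
    double mask12 = corrected ? 1.0 - fb2[j] : fb2[j];
    double val = Ap1 * (fp11[j] * fb2[j] / m11 + fp12[j] * mask12 / m12) + Ap4;
    if (Ap2 > 0.0) val += Ap2 * fp23[j] / m23;
    if (Ap3 > 0.0) val += Ap3 * g[i] / mg;
    P[i] = val;
  }
  return P;
}
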