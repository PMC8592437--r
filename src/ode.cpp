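// Adaptive Cash-Karp RK45 forward simulation of the AML and CML treatment
// models. Dose is piecewise constant; discontinuities are handled by
// integrating segment-wise between dose breakpoints, so the integrator only
// ever sees a smooth right-hand side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

typedef void (*rhs_fn)(double t, const double* y, double* dy,
                       const double* p, double dose);

// state: (Q_H, A_H, Q_L, A_L); params: tQA_H, tAQ_H, p_H, d_H,
// tQA_L, tAQ_L, p_L, d_L, K_Q, K_A, c.  dose = u(t) in {0, 1}.
static void aml_rhs_c(double t, const double* y, double* dy,
                      const double* p, double dose) {
  const double QH = y[0], AH = y[1], QL = y[2], AL = y[3];
  const double occQ = 1.0 - (QH + QL) / p[8];
  const double occA = 1.0 - (AH + AL) / p[9];
  const double kill = p[10] * dose;
  const double fH = p[0] * QH * occA - p[1] * AH * occQ; // net Q_H -> A_H
  const double fL = p[4] * QL * occA - p[5] * AL * occQ;
  dy[0] = -fH;
  dy[1] = fH + p[2] * AH * occA - p[3] * AH - kill * AH;
  dy[2] = -fL;
  dy[3] = fL + p[6] * AL * occA - p[7] * AL - kill * AL;
}

// state: (X, Y, Z); params: p_XY, p_YX, p_Y, K_Y, e_TKI, m, p_Z, K_Z, r_Z, a.
// dose in {1, 0.5, 0}.
static void cml_rhs_c(double t, const double* y, double* dy,
                      const double* p, double dose) {
  const double X = y[0], Y = y[1], Z = y[2];
  const double flow = p[0] * X - p[1] * Y; // net X -> Y
  dy[0] = -flow;
  dy[1] = flow + p[2] * Y * (1.0 - Y / p[3]) - p[4] * dose * Y - p[5] * Y * Z;
  dy[2] = p[8] - p[9] * Z + p[6] * Z * Y / (p[7] + Y * Y);
}

// Cash-Karp tableau
static const double CK_A[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0 / 5, 0, 0, 0, 0},
  {3.0 / 40, 9.0 / 40, 0, 0, 0},
  {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
  {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
  {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592, 253.0 / 4096}};
static const double CK_B5[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594,
                                0, 512.0 / 1771};
static const double CK_B4[6] = {2825.0 / 27648, 0, 18575.0 / 48384,
                                13525.0 / 55296, 277.0 / 14336, 1.0 / 4};

// Integrate y over [t0, t1] with constant dose, overwriting y in place.
// *hio carries the adaptive step size across segments (<= 0: no estimate).
static void integrate_segment(rhs_fn f, double t0, double t1, double* y,
                              int n, const double* p, double dose,
                              double rtol, double atol, double* hio) {
  if (t1 <= t0) return;
  double t = t0;
  double h = (*hio > 0) ? std::min(*hio, t1 - t0) : (t1 - t0) / 10.0;
  if (h <= 0) return;
  double k[6][4], ytmp[4], y5[4], y4[4];
  int iter = 0;
  while (t < t1) {
    if (++iter > 1000000)
      stop("ODE integration failed to advance (too many steps) at t=%g", t);
    if (t + h > t1) h = t1 - t;
    for (int s = 0; s < 6; ++s) {
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += CK_A[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      f(t, ytmp, k[s], p, dose);
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(k[s][i]))
          stop("non-finite derivative: simulation blow-up at t=%g", t);
    }
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double s5 = 0.0, s4 = 0.0;
      for (int s = 0; s < 6; ++s) {
        s5 += CK_B5[s] * k[s][i];
        s4 += CK_B4[s] * k[s][i];
      }
      y5[i] = y[i] + h * s5;
      y4[i] = y[i] + h * s4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      errmax = std::max(errmax, std::fabs(y5[i] - y4[i]) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < n; ++i) y[i] = y5[i];
      double fac = (errmax > 1e-12) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, fac);
      *hio = h;
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (h < 1e-12 * (t1 - t0))
      stop("ODE step size underflow at t=%g (stiff or blown-up system)", t);
  }
}

// Shared driver: piecewise-constant dose given by breakpoints dose_t
// (ascending, dose_t[0] <= 0 assumed start) and values dose_v, where
// dose_v[i] applies on [dose_t[i], dose_t[i+1]) and dose_v[last] to +Inf.
static NumericMatrix sim_driver(rhs_fn f, int n, NumericVector params,
                                NumericVector state0, NumericVector times,
                                NumericVector dose_t, NumericVector dose_v,
                                double rtol, double atol) {
  const int nt = times.size();
  NumericMatrix out(nt, n);
  double y[4];
  for (int i = 0; i < n; ++i) y[i] = state0[i];
  const double* p = REAL(params);

  // merged event times: output grid + dose breakpoints
  std::vector<double> ev;
  for (int i = 0; i < dose_t.size(); ++i)
    if (dose_t[i] > 0) ev.push_back(dose_t[i]);
  for (int i = 0; i < nt; ++i) ev.push_back(times[i]);
  std::sort(ev.begin(), ev.end());

  double t = 0.0;
  double hio = -1.0;
  double last_dose = NA_REAL;
  int iout = 0;
  while (iout < nt && times[iout] <= 0.0) { // report initial state at t<=0
    for (int i = 0; i < n; ++i) out(iout, i) = y[i];
    ++iout;
  }
  for (size_t e = 0; e < ev.size(); ++e) {
    double te = ev[e];
    if (te <= t) continue;
    // dose on (t, te): value at segment midpoint
    double tm = 0.5 * (t + te), dose = dose_v[dose_v.size() - 1];
    for (int i = dose_t.size() - 1; i >= 0; --i)
      if (tm >= dose_t[i]) { dose = dose_v[i]; break; }
    if (dose != last_dose) hio = -1.0;  // dose jump: re-estimate the step
    last_dose = dose;
    integrate_segment(f, t, te, y, n, p, dose, rtol, atol, &hio);
    t = te;
    while (iout < nt && times[iout] <= t + 1e-12) {
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_aml_cpp")]]
NumericMatrix sim_aml_cpp(NumericVector params, NumericVector state0,
                          NumericVector times, NumericVector dose_t,
                          NumericVector dose_v, double rtol = 1e-8,
                          double atol = 1e-8) {
  if (params.size() != 11) stop("AML parameter vector must have 11 entries");
  if (state0.size() != 4) stop("AML state must have 4 entries");
  return sim_driver(aml_rhs_c, 4, params, state0, times, dose_t, dose_v,
                    rtol, atol);
}

//' @noRd
// [[Rcpp::export(name = ".sim_cml_cpp")]]
NumericMatrix sim_cml_cpp(NumericVector params, NumericVector state0,
                          NumericVector times, NumericVector dose_t,
                          NumericVector dose_v, double rtol = 1e-8,
                          double atol = 1e-10) {
  if (params.size() != 10) stop("CML rate vector must have 10 entries");
  if (state0.size() != 3) stop("CML state must have 3 entries");
  return sim_driver(cml_rhs_c, 3, params, state0, times, dose_t, dose_v,
                    rtol, atol);
}
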