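#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// x^p with the convention 0^p = 0 for any p > 0 (and for negative x, which
// the caller has already clamped or treats as 0).  Needed because fractional
// powers of the density enter the mortality law and the state can touch 0.
static inline double pow_safe(double x, double p) {
  if (x <= 0.0) return 0.0;
  return std::pow(x, p);
}

// Unified right-hand side of all model variants.
//   growth_i  = b_i x_i (1 - x_i - sum_{j!=i} alpha_ij T(x_j)),
//               T(x) = x (linear competition) or x^2 (squared competition)
//   mortality = (m0_i + d_i x_i^delta) x_i        crowding law
//             = (m0_i + d_i) x_i                  delta = 0 degenerate mode
//             = m0_i x_i^(1+eps)                  aggregation law
static void rhs_eval(const double* x, double* f, int n,
                     const double* b, const double* m0, const double* d,
                     double delta, double eps, const double* alpha,
                     bool square_comp, bool agg_mort, bool delta_zero) {
  for (int i = 0; i < n; ++i) {
    double xi = x[i] > 0.0 ? x[i] : 0.0;
    double comp = xi;  // own-density term is always linear (alpha_ii = 1)
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double xj = x[j] > 0.0 ? x[j] : 0.0;
      comp += alpha[i + n * j] * (square_comp ? xj * xj : xj);
    }
    double growth = b[i] * xi * (1.0 - comp);
    double mort;
    if (agg_mort) {
      mort = m0[i] * pow_safe(xi, 1.0 + eps);
    } else {
      double m = delta_zero ? (m0[i] + d[i])
                            : (m0[i] + d[i] * pow_safe(xi, delta));
      mort = m * xi;
    }
    f[i] = growth - mort;
  }
}

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector x, NumericVector b, NumericVector m0,
                      NumericVector d, double delta, double eps,
                      NumericMatrix alpha, bool square_comp, bool agg_mort,
                      bool delta_zero) {
  int n = x.size();
  NumericVector f(n);
  rhs_eval(x.begin(), f.begin(), n, b.begin(), m0.begin(), d.begin(),
           delta, eps, alpha.begin(), square_comp, agg_mort, delta_zero);
  return f;
}

// Dormand-Prince 5(4) coefficients
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

// Adaptive Dormand-Prince 5(4) integration of one model variant, reporting
// the state at each requested output time (steps are shortened to land on
// them exactly).  Negative components are clamped to zero after every
// accepted step; the largest clamped magnitude is reported so callers can
// flag overshoot beyond 1e-9.
// [[Rcpp::export]]
List cpp_integrate(NumericVector x0, NumericVector times, NumericVector b,
                   NumericVector m0, NumericVector d, double delta,
                   double eps, NumericMatrix alpha, bool square_comp,
                   bool agg_mort, bool delta_zero, double rtol, double atol,
                   double steady_tol, bool early_exit, double max_steps) {
  const int n = x0.size(), nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> y(x0.begin(), x0.end());
  std::vector<double> ytmp(n), ynew(n), yerr(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n);
  const double* al = alpha.begin();
  const double* pb = b.begin();
  const double* pm = m0.begin();
  const double* pd = d.begin();

#define RHS(xx, ff) rhs_eval(xx.data(), ff.data(), n, pb, pm, pd, delta, \
                             eps, al, square_comp, agg_mort, delta_zero)

  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];
  int iout = 1;
  double max_clamp = 0.0;
  long steps = 0;
  int status = 0;  // 0 ok, 1 early steady exit, 2 step underflow, 3 max steps
  double steady_time = NA_REAL;

  RHS(y, k1);
  double h = 1e-4;
  const double tend = times[nt - 1];
  const double hmin = 1e-14 * std::max(1.0, std::fabs(tend));

  while (iout < nt) {
    if (steps++ > max_steps) { status = 3; break; }
    bool hit = false;
    if (t + h >= times[iout]) { h = times[iout] - t; hit = true; }
    if (h < hmin) { status = 2; break; }

    // stage computations (FSAL: k1 already holds f(t, y))
    for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    RHS(ytmp, k2);
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    RHS(ytmp, k3);
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    RHS(ytmp, k4);
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                            a54 * k4[j]);
    RHS(ytmp, k5);
    for (int j = 0; j < n; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    RHS(ytmp, k6);
    for (int j = 0; j < n; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    RHS(ynew, k7);
    for (int j = 0; j < n; ++j) {
      double y4 = y[j] + h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                              e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
      yerr[j] = ynew[j] - y4;
    }

    double err = 0.0;
    for (int j = 0; j < n; ++j) {
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double r = yerr[j] / sc;
      err += r * r;
    }
    err = std::sqrt(err / n);

    if (err <= 1.0) {  // accept
      t += h;
      for (int j = 0; j < n; ++j) {
        if (ynew[j] < 0.0) {
          double mag = -ynew[j];
          if (mag > max_clamp) max_clamp = mag;
          ynew[j] = 0.0;
        }
        y[j] = ynew[j];
      }
      RHS(y, k1);  // refresh FSAL derivative after clamping
      if (hit) {
        for (int j = 0; j < n; ++j) out(iout, j) = y[j];
        ++iout;
      }
      if (early_exit && steady_tol > 0.0) {
        double mx = 0.0;
        for (int j = 0; j < n; ++j) mx = std::max(mx, std::fabs(k1[j]));
        if (mx < steady_tol) {
          status = 1;
          steady_time = t;
          break;
        }
      }
      double fac = err > 0.0 ? 0.9 * std::pow(err, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.2, fac));
      h = std::min(h * fac, tend - t > 0 ? tend - t : h);
      if (h <= 0) h = hmin * 10;
    } else {  // reject
      double fac = std::max(0.2, 0.9 * std::pow(err, -0.2));
      h *= fac;
      if (h < hmin) { status = 2; break; }
    }
  }
#undef RHS

  return List::create(_["states"] = out, _["n_filled"] = iout,
                      _["steps"] = (double)steps, _["max_clamp"] = max_clamp,
                      _["status"] = status, _["t_end"] = t,
                      _["steady_time"] = steady_time);
}
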