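#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Sparse (CSR) matrix-vector product y = alpha * N for the full interaction
// matrix (unit diagonal included in the CSR arrays).
static inline void csr_matvec(const int n, const int *row_ptr, const int *col,
                              const double *val, const double *x, double *y) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = row_ptr[i]; k < row_ptr[i + 1]; ++k) acc += val[k] * x[col[k]];
    y[i] = acc;
  }
}

// dN_i/dt = r_i N_i (1 - (alpha N)_i) + lambda
static inline double deriv(const int n, const int *row_ptr, const int *col,
                           const double *val, const double *r, const double lambda,
                           const double *N, double *work, double *dN) {
  csr_matvec(n, row_ptr, col, val, N, work);
  double dmax = 0.0;
  for (int i = 0; i < n; ++i) {
    dN[i] = r[i] * N[i] * (1.0 - work[i]) + lambda;
    double a = std::fabs(dN[i]);
    if (a > dmax) dmax = a;
  }
  return dmax;
}

static inline double lyapunov(const int n, const int *row_ptr, const int *col,
                              const double *val, const double *N, double *work) {
  csr_matvec(n, row_ptr, col, val, N, work);
  double f = 0.0;
  for (int i = 0; i < n; ++i) f += 2.0 * N[i] - N[i] * work[i];
  return f;
}

// Cash-Karp embedded Runge-Kutta 4(5) with adaptive step size.
// Integrates until max_i |dN_i/dt| < deriv_tol or t reaches t_end.
// Abundances are clamped at zero after every accepted step (with lambda > 0
// they stay positive; the clamp guards against integrator undershoot).
// [[Rcpp::export]]
List lv_integrate_cpp(NumericVector N0, IntegerVector row_ptr, IntegerVector col_idx,
                      NumericVector values, NumericVector growth, double lambda,
                      double t0, double t_end, double deriv_tol,
                      double rtol, double atol, int max_steps,
                      int record_lyapunov) {
  const int n = N0.size();
  const int *rp = row_ptr.begin();
  const int *ci = col_idx.begin();
  const double *vx = values.begin();
  const double *r = growth.begin();

  std::vector<double> N(N0.begin(), N0.end());
  std::vector<double> work(n), k1(n), k2(n), k3(n), k4(n), k5(n), k6(n),
      tmp(n), N5(n), N4(n);

  // Cash-Karp tableau
  const double b21 = 1.0 / 5.0;
  const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
               b54 = 35.0 / 27.0;
  const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
               b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
  const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
               c6 = 512.0 / 1771.0;
  const double d1 = 2825.0 / 27648.0, d3 = 18575.0 / 48384.0,
               d4 = 13525.0 / 55296.0, d5 = 277.0 / 14336.0, d6 = 1.0 / 4.0;

  double t = t0, dt = 1e-3;
  int steps = 0;
  bool converged = false;
  double dmax = deriv(n, rp, ci, vx, r, lambda, N.data(), work.data(), k1.data());
  if (dmax < deriv_tol) converged = true;

  // Lyapunov trace with doubling-stride thinning (bounded memory)
  std::vector<double> f_t, f_v;
  int stride = 1, since = 0;
  const int cap = 4096;
  if (record_lyapunov) {
    f_t.push_back(t);
    f_v.push_back(lyapunov(n, rp, ci, vx, N.data(), work.data()));
  }

  while (!converged && t < t_end && steps < max_steps) {
    if (t + dt > t_end) dt = t_end - t;

    // k1 already holds f(N)
    for (int i = 0; i < n; ++i) tmp[i] = N[i] + dt * b21 * k1[i];
    deriv(n, rp, ci, vx, r, lambda, tmp.data(), work.data(), k2.data());
    for (int i = 0; i < n; ++i) tmp[i] = N[i] + dt * (b31 * k1[i] + b32 * k2[i]);
    deriv(n, rp, ci, vx, r, lambda, tmp.data(), work.data(), k3.data());
    for (int i = 0; i < n; ++i)
      tmp[i] = N[i] + dt * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    deriv(n, rp, ci, vx, r, lambda, tmp.data(), work.data(), k4.data());
    for (int i = 0; i < n; ++i)
      tmp[i] = N[i] + dt * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    deriv(n, rp, ci, vx, r, lambda, tmp.data(), work.data(), k5.data());
    for (int i = 0; i < n; ++i)
      tmp[i] = N[i] + dt * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    deriv(n, rp, ci, vx, r, lambda, tmp.data(), work.data(), k6.data());

    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      N5[i] = N[i] + dt * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      N4[i] = N[i] + dt * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                           d6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(N[i]), std::fabs(N5[i]));
      double e = std::fabs(N5[i] - N4[i]) / sc;
      if (e > errmax) errmax = e;
    }

    if (errmax <= 1.0) {  // accept
      t += dt;
      for (int i = 0; i < n; ++i) N[i] = (N5[i] < 0.0) ? 0.0 : N5[i];
      dmax = deriv(n, rp, ci, vx, r, lambda, N.data(), work.data(), k1.data());
      if (dmax < deriv_tol) converged = true;
      if (record_lyapunov && (++since >= stride || converged)) {
        since = 0;
        f_t.push_back(t);
        f_v.push_back(lyapunov(n, rp, ci, vx, N.data(), work.data()));
        if ((int)f_t.size() >= cap) {  // thin: keep every other record
          std::vector<double> tt, vv;
          for (size_t j = 0; j < f_t.size(); j += 2) {
            tt.push_back(f_t[j]);
            vv.push_back(f_v[j]);
          }
          f_t.swap(tt);
          f_v.swap(vv);
          stride *= 2;
        }
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      dt *= std::min(5.0, std::max(0.2, fac));
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      dt *= std::max(0.1, fac);
    }
    if (dt < 1e-14) dt = 1e-14;
    ++steps;
    if ((steps & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["N"] = NumericVector(N.begin(), N.end()),
                      _["t"] = t, _["steps"] = steps,
                      _["max_rate"] = dmax, _["converged"] = converged,
                      _["lyapunov_t"] = NumericVector(f_t.begin(), f_t.end()),
                      _["lyapunov"] = NumericVector(f_v.begin(), f_v.end()));
}
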