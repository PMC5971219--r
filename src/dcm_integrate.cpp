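// Fixed-step RK4 integration of the coupled neuronal/hemodynamic state
// system of a bilinear DCM.
//
// States per region: z (neuronal), s (vasodilatory signal), f (inflow),
// v (venous volume), q (deoxyhemoglobin).  Inputs u(t) are supplied on
// their own uniform grid and linearly interpolated at stage times, so the
// input discretisation is independent of the integration step.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Model {
  int n, m;
  const double *A;      // n x n, column-major
  const double *B;      // n x n x m
  const double *C;      // n x m
  const double *ks, *ga, *tau, *alpha, *E0;
  const double *log1mE0;
  const double *u;      // m x nu, column-major (row = input)
  int nu;
  double dt_u;
};

inline void inputsAt(const Model &M, double t, double *ui) {
  double x = t / M.dt_u;
  int k = (int)std::floor(x);
  if (k < 0) { k = 0; x = 0.0; }
  if (k >= M.nu - 1) { k = M.nu - 2; x = (double)(M.nu - 1); }
  double w = x - k;
  for (int j = 0; j < M.m; ++j) {
    double u0 = M.u[j + (size_t)k * M.m];
    double u1 = M.u[j + (size_t)(k + 1) * M.m];
    ui[j] = u0 + w * (u1 - u0);
  }
}

// state layout: [z(n), s(n), f(n), v(n), q(n)]
inline bool deriv(const Model &M, double t, const double *x, double *dx,
                  std::vector<double> &ui) {
  const int n = M.n;
  const double *z = x, *s = x + n, *f = x + 2 * n, *v = x + 3 * n, *q = x + 4 * n;
  inputsAt(M, t, ui.data());
  for (int i = 0; i < n; ++i) {
    // dz = (A + sum_j u_j B_j) z + C u
    double acc = 0.0;
    for (int k = 0; k < n; ++k) {
      double a = M.A[i + k * n];
      for (int j = 0; j < M.m; ++j)
        a += ui[j] * M.B[i + k * n + (size_t)j * n * n];
      acc += a * z[k];
    }
    for (int j = 0; j < M.m; ++j) acc += M.C[i + j * n] * ui[j];
    dx[i] = acc;

    if (f[i] <= 0.0 || v[i] <= 0.0 || q[i] <= 0.0) return false;
    dx[n + i] = z[i] - M.ks[i] * s[i] - M.ga[i] * (f[i] - 1.0);
    dx[2 * n + i] = s[i];
    // v^(1/alpha) and (1-E0)^(1/f) via exp/log (cheaper than pow here)
    double vexp = std::exp(std::log(v[i]) / M.alpha[i]);
    dx[3 * n + i] = (f[i] - vexp) / M.tau[i];
    double ext = (1.0 - std::exp(M.log1mE0[i] / f[i])) / M.E0[i];
    dx[4 * n + i] = (f[i] * ext - vexp * q[i] / v[i]) / M.tau[i];
  }
  return true;
}

inline bool rk4step(const Model &M, double t, double h, double *x,
                    std::vector<double> &k1, std::vector<double> &k2,
                    std::vector<double> &k3, std::vector<double> &k4,
                    std::vector<double> &tmp, std::vector<double> &ui) {
  const int d = 5 * M.n;
  if (!deriv(M, t, x, k1.data(), ui)) return false;
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * h * k1[i];
  if (!deriv(M, t + 0.5 * h, tmp.data(), k2.data(), ui)) return false;
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + 0.5 * h * k2[i];
  if (!deriv(M, t + 0.5 * h, tmp.data(), k3.data(), ui)) return false;
  for (int i = 0; i < d; ++i) tmp[i] = x[i] + h * k3[i];
  if (!deriv(M, t + h, tmp.data(), k4.data(), ui)) return false;
  for (int i = 0; i < d; ++i)
    x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
  // reject states driven non-positive; caller retries with substeps
  for (int i = 2 * M.n; i < d; ++i)
    if (x[i] <= 0.0) return false;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List dcm_integrate_cpp(NumericMatrix A, NumericVector Bflat, NumericMatrix C,
                       NumericVector ks, NumericVector ga, NumericVector tau,
                       NumericVector alpha, NumericVector E0,
                       NumericMatrix u, double dt_u,
                       double dt, int nSteps, int outEvery,
                       int outMode = 0) {
  const int n = A.nrow();
  const int m = C.ncol();
  Model M;
  M.n = n; M.m = m;
  M.A = A.begin(); M.B = Bflat.begin(); M.C = C.begin();
  M.ks = ks.begin(); M.ga = ga.begin(); M.tau = tau.begin();
  M.alpha = alpha.begin(); M.E0 = E0.begin();
  std::vector<double> log1mE0(n);
  for (int i = 0; i < n; ++i) log1mE0[i] = std::log(1.0 - E0[i]);
  M.log1mE0 = log1mE0.data();
  M.u = u.begin(); M.nu = u.ncol(); M.dt_u = dt_u;

  const int d = 5 * n;
  std::vector<double> x(d), k1(d), k2(d), k3(d), k4(d), tmp(d), ui(m);
  for (int i = 0; i < n; ++i) {
    x[i] = 0.0; x[n + i] = 0.0; x[2 * n + i] = 1.0; x[3 * n + i] = 1.0; x[4 * n + i] = 1.0;
  }

  // outMode 0: all states; 1: only v and q (the observation inputs)
  const int nOut = nSteps / outEvery + 1;
  const int rowLo = (outMode == 1) ? 3 * n : 0;
  const int nRows = (outMode == 1) ? 2 * n : d;
  NumericMatrix out(nRows, nOut);
  NumericVector tout(nOut);
  for (int i = 0; i < nRows; ++i) out(i, 0) = x[rowLo + i];
  tout[0] = 0.0;
  int col = 1;
  bool ok = true;
  std::string msg;

  std::vector<double> save(d);
  for (int step = 0; step < nSteps && ok; ++step) {
    double t = step * dt;
    save = x;
    if (!rk4step(M, t, dt, x.data(), k1, k2, k3, k4, tmp, ui)) {
      // retry with 4 substeps if a state went non-positive mid-step
      x = save;
      bool sub_ok = true;
      for (int ss = 0; ss < 4 && sub_ok; ++ss)
        sub_ok = rk4step(M, t + ss * dt / 4.0, dt / 4.0, x.data(),
                         k1, k2, k3, k4, tmp, ui);
      if (!sub_ok) { ok = false; msg = "hemodynamic state became non-positive"; break; }
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e3) {
        ok = false; msg = "neuronal state diverged (|z| > 1e3)"; break;
      }
    }
    if (!ok) break;
    if ((step + 1) % outEvery == 0 && col < nOut) {
      for (int i = 0; i < nRows; ++i) out(i, col) = x[rowLo + i];
      tout[col] = (step + 1) * dt;
      ++col;
    }
  }

  return List::create(_["states"] = out, _["time"] = tout, _["ok"] = ok,
                      _["message"] = msg);
}
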