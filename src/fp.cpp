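#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Crank-Nicolson propagation of the advection-diffusion equation
//   dp/dt = -v(t) dp/dx + D d2p/dx2
// on a uniform grid with absorbing (p = 0) boundaries at both ends.
// The last node is the decision threshold; the first node is the far
// boundary, placed far enough away that the mass reaching it is
// negligible (it is monitored via the leak flux integral).
// v has one entry per time node (nt + 1 values for nt steps).
// [[Rcpp::export]]
List fp_cn_cpp(NumericVector v, double D, double dt, double dx,
               NumericVector p_init, int save_every) {
  const int nx = p_init.size();
  const int nt = v.size() - 1;
  if (nx < 5) stop("grid too small");
  std::vector<double> p(p_init.begin(), p_init.end());
  p[0] = 0.0; p[nx - 1] = 0.0;

  const double dif = D / (dx * dx);
  const double r = dt / 2.0;
  const int ni = nx - 2;                       // interior unknowns
  std::vector<double> sub(ni), dia(ni), sup(ni), rhs(ni), cp(ni), dp(ni);

  NumericVector surv(nt + 1), flux_abs(nt + 1), leak_cum(nt + 1);
  int n_snap = nt / save_every + 1;
  NumericMatrix snaps(nx, n_snap);
  NumericVector snap_step(n_snap);
  int isnap = 0;

  double mass0 = 0.0;
  for (int i = 0; i < nx; ++i) mass0 += p[i];
  surv[0] = mass0 * dx;
  flux_abs[0] = D * (4.0 * p[nx - 2] - p[nx - 3]) / (2.0 * dx);
  leak_cum[0] = 0.0;
  for (int i = 0; i < nx; ++i) snaps(i, 0) = p[i];
  snap_step[0] = 0; isnap = 1;

  double leak = 0.0;
  for (int n = 0; n < nt; ++n) {
    const double w0 = v[n] / (2.0 * dx), w1 = v[n + 1] / (2.0 * dx);
    // rhs = (I + r L(t_n)) p
    for (int i = 1; i <= nx - 2; ++i) {
      double lp = (dif + w0) * p[i - 1] - 2.0 * dif * p[i] + (dif - w0) * p[i + 1];
      rhs[i - 1] = p[i] + r * lp;
    }
    // (I - r L(t_{n+1})) p_new = rhs ; boundary values are zero
    for (int j = 0; j < ni; ++j) {
      sub[j] = -r * (dif + w1);
      dia[j] = 1.0 + 2.0 * r * dif;
      sup[j] = -r * (dif - w1);
    }
    // Thomas solve
    cp[0] = sup[0] / dia[0];
    dp[0] = rhs[0] / dia[0];
    for (int j = 1; j < ni; ++j) {
      double m = dia[j] - sub[j] * cp[j - 1];
      cp[j] = sup[j] / m;
      dp[j] = (rhs[j] - sub[j] * dp[j - 1]) / m;
    }
    p[nx - 2] = dp[ni - 1];
    for (int j = ni - 2; j >= 0; --j) p[j + 1] = dp[j] - cp[j] * p[j + 2];
    p[0] = 0.0; p[nx - 1] = 0.0;

    double mass = 0.0;
    for (int i = 0; i < nx; ++i) { if (p[i] < 0.0 && p[i] > -1e-14) p[i] = 0.0; mass += p[i]; }
    surv[n + 1] = mass * dx;
    flux_abs[n + 1] = D * (4.0 * p[nx - 2] - p[nx - 3]) / (2.0 * dx);
    double leak_flux = D * (4.0 * p[1] - p[2]) / (2.0 * dx);
    leak += dt * leak_flux;
    leak_cum[n + 1] = leak;
    if ((n + 1) % save_every == 0 && isnap < n_snap) {
      for (int i = 0; i < nx; ++i) snaps(i, isnap) = p[i];
      snap_step[isnap] = n + 1;
      ++isnap;
    }
  }

  return List::create(_["survival"] = surv, _["flux_abs"] = flux_abs,
                      _["leak_cum"] = leak_cum,
                      _["snapshots"] = snaps, _["snap_step"] = snap_step,
                      _["p_final"] = wrap(p));
}
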