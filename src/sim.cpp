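#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double utility_val(int form, double beta, double ufloor, double E) {
  if (form == 0) return 1.0;
  double e = E > 0.0 ? E : 0.0;
  if (form == 1) return (1.0 - ufloor) * std::exp(-beta * e) + ufloor;
  double u = 1.0 - beta * e;                 // threshold-linear
  return u > ufloor ? u : ufloor;
}

// Gaussian draw truncated to (0, Inf) by resampling (same contract and
// RNG consumption as the R-level draw_patch helper).
static inline double draw_positive(double mean, double sd) {
  if (sd <= 0.0) return mean;
  for (int i = 0; i < 1000; ++i) {
    double x = R::rnorm(mean, sd);
    if (x > 0.0) return x;
  }
  stop("could not draw a positive patch parameter after 1000 attempts");
  return NA_REAL; // not reached
}

// Full foraging session: alternating patch and travel phases.
// Visits are recorded only for completed patch+travel cycles; the caller
// applies the burn-in window.  RNG call order matches the R reference
// step functions exactly, so trajectories are reproducible from R seeds.
// [[Rcpp::export]]
List sim_session_cpp(double rho0_mean, double rho0_sd, double A_mean, double A_sd,
                     double c, double ttr_mean, bool ttr_exp, double s,
                     double rho0_bar, double A_bar,
                     bool size_adaptive, double alpha_fixed,
                     double tau, double tau_E, double sigma, double dt,
                     int u_form, double u_beta, double u_floor,
                     double total_time, double e_init,
                     bool freeze_E, bool update_each_step, int max_patches) {
  std::vector<double> v_enter, v_leave, v_food, v_Eexit, v_trav, v_rho0, v_Aa;
  std::vector<int> v_chunks, v_degen;
  double t = 0.0, E = e_init;
  double sqdt = std::sqrt(dt);
  bool ended = false;
  int n_degen_total = 0;

  for (int p = 0; p < max_patches && !ended; ++p) {
    double rho0 = draw_positive(rho0_mean, rho0_sd);
    double Ap = draw_positive(A_mean, A_sd);
    double t_enter = t, rho = rho0, x = 0.0, food_tot = 0.0;
    int chunks = 0, degen = 0;
    bool left = false, have_rule = false;
    double alpha = alpha_fixed, eta = 0.0;

    while (!left) {
      if (update_each_step || !have_rule) {
        if (E + s >= rho0_bar) { degen = 1; ++n_degen_total; break; }
        double L = std::log(rho0_bar / (E + s));
        alpha = size_adaptive ? (rho0_bar - E - s) / L : alpha_fixed;
        eta = A_bar * (alpha * L - rho0_bar + E + s);
        have_rule = true;
      }
      double food = 0.0;
      if (c > 0.0) {
        int k = (int) R::rpois(rho * dt / c);
        food = k * c;
        double avail = rho * Ap;
        if (food > avail) food = avail;
        chunks += k;
      } else {
        food = rho * dt;
      }
      double z = (sigma > 0.0) ? R::norm_rand() : 0.0;
      double u = utility_val(u_form, u_beta, u_floor, E);
      double sgn = (eta >= 0.0) ? 1.0 : -1.0;
      x += (alpha * u * dt - food * std::pow(u, -sgn)) / tau
           + (sigma / tau) * sqdt * z;
      if (!freeze_E) E += dt * (-s - E) / tau_E + food / tau_E;
      rho -= food / Ap; if (rho < 0.0) rho = 0.0;
      food_tot += food;
      t += dt;
      if ((eta >= 0.0 && x >= eta) || (eta < 0.0 && x <= eta)) left = true;
      else if (t >= total_time) { ended = true; break; }
    }
    if (ended) break;

    double t_leave = t, E_exit = E;
    double Ttr = ttr_exp ? R::exp_rand() * ttr_mean : ttr_mean;
    if (t_leave + Ttr > total_time) { ended = true; break; }
    double tp = 0.0;
    while (Ttr - tp > 1e-12) {
      double h = dt < (Ttr - tp) ? dt : (Ttr - tp);
      if (!freeze_E) E += h * (-s - E) / tau_E;
      tp += h; t += h;
    }
    v_enter.push_back(t_enter);  v_leave.push_back(t_leave);
    v_food.push_back(food_tot);  v_chunks.push_back(chunks);
    v_Eexit.push_back(E_exit);   v_trav.push_back(Ttr);
    v_rho0.push_back(rho0);      v_Aa.push_back(Ap);
    v_degen.push_back(degen);
    if (t >= total_time) break;
  }

  return List::create(
    _["t_enter"] = wrap(v_enter), _["t_leave"] = wrap(v_leave),
    _["food"] = wrap(v_food), _["chunks"] = wrap(v_chunks),
    _["E_exit"] = wrap(v_Eexit), _["travel_after"] = wrap(v_trav),
    _["rho0_actual"] = wrap(v_rho0), _["A_actual"] = wrap(v_Aa),
    _["degenerate"] = wrap(v_degen), _["n_degenerate"] = n_degen_total,
    _["t_final"] = t);
}

// Single-patch first-passage sampler with the energy estimate (and hence
// the threshold) frozen: used for distribution-level validation against
// the Fokker-Planck solver and for counting-strategy properties.
// exact_decay = true uses the deterministic mean reward rho0*exp(-t/A)
// (the continuous-reward SDE the Fokker-Planck problem describes);
// otherwise rewards are Poisson chunks from a depleting patch (c > 0)
// or Euler-depleted continuous rewards (c = 0).
// [[Rcpp::export]]
List fpt_sample_cpp(int n, double alpha, double eta, double sigma, double tau,
                    double rho0, double A, double c, double dt, double t_max,
                    bool exact_decay) {
  NumericVector T(n), Food(n);
  IntegerVector K(n);
  double sqdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double x = 0.0, t = 0.0, rho = rho0, food_tot = 0.0;
    int k_tot = 0;
    bool hit = false;
    while (t < t_max) {
      double food;
      if (c > 0.0) {
        int k = (int) R::rpois(rho * dt / c);
        food = k * c;
        double avail = rho * A;
        if (food > avail) food = avail;
        k_tot += k;
        rho -= food / A; if (rho < 0.0) rho = 0.0;
      } else if (exact_decay) {
        food = rho0 * std::exp(-t / A) * dt;
      } else {
        food = rho * dt;
        rho -= food / A; if (rho < 0.0) rho = 0.0;
      }
      double z = (sigma > 0.0) ? R::norm_rand() : 0.0;
      x += (alpha * dt - food) / tau + (sigma / tau) * sqdt * z;
      t += dt;
      food_tot += food;
      if ((eta >= 0.0 && x >= eta) || (eta < 0.0 && x <= eta)) { hit = true; break; }
    }
    T[i] = hit ? t : NA_REAL;
    Food[i] = food_tot;
    K[i] = k_tot;
  }
  return List::create(_["t"] = T, _["food"] = Food, _["chunks"] = K);
}
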