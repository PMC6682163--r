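# forageDDM

Drift-diffusion modelling of patch-leaving foraging decisions.

## The problem

A forager exploits a food patch that depletes as it eats, and must decide
when to abandon it and travel to the next one.  Classical behavioral
ecology answers with the **marginal value theorem (MVT)**: leave when the
instantaneous net intake rate in the patch falls to the average net rate
the whole environment affords.  But the MVT is silent about *mechanism* —
real animals sample a noisy, chunky reward stream and must decide from
imperfect evidence.

`forageDDM` implements a mechanistic account that couples two stochastic
processes:

- an **energy estimate** `E`, an exponential moving average of the net
  intake rate, with timescale `tau_E`:

  `tau_E dE = (r(t) - s - E) dt`

- a **patch decision variable** `x`, a drift-diffusion accumulator that
  starts at 0 on patch entry and triggers leaving when it reaches a
  threshold `eta`:

  `tau dx = (alpha - r(t)) dt + sigma dW(t)`

Here `r(t)` is the reward stream from the current patch (Poisson chunks of
size `c` at rate `rho(t)/c`, with the patch density decaying on average as
`rho_0 e^{-t/A}`), `s` is a constant metabolic cost, `alpha` a drift rate
and `sigma` the decision noise.  Tying the threshold to the drift by

`eta = A (alpha log(rho_0/(E+s)) - rho_0 + E + s)`

makes the accumulator exactly equivalent to the MVT in the noiseless,
continuous-reward limit — for *any* valid drift.  Different drift choices
are therefore different **strategies** with identical optimal behavior but
different responses to uncertainty: density-adaptive (`alpha = rho_0`),
size-adaptive (threshold zero), counting (`alpha = 0`: leave after a fixed
amount of food) and robust counting (`alpha < 0`).  A satisficing marginal
utility `u(E)` can modulate the dynamics to reproduce the ubiquitous
observation that animals stay in patches longer than the MVT predicts when
food is plentiful.

The package provides:

- `solve_environment()`, `optimal_patch_time()`, `optimal_threshold()`,
  `strategy_params()`, `drift_validity()`, `n_opt()`,
  `prt_sensitivity_density()`/`prt_sensitivity_size()` and
  `utility_fixed_point()` — the closed-form / root-finding analytics layer;
- `simulate_session()` and `sweep_sessions()` — a compiled full-session
  simulator with the burn-in and full-cycle averaging conventions built in;
- `fp_problem()`, `solve_density()`, `first_passage_stats()` and
  `sample_leave_times()` — a Crank-Nicolson Fokker-Planck solver for the
  patch-leaving time distribution, with a Monte-Carlo counterpart;
- `parse_config()` / `fddm_main()` and the `inst/exec/forageddm` script —
  a configuration-driven command-line interface.

It is aimed at behavioral ecologists and computational neuroscientists who
want a tested, reproducible simulator of evidence-accumulation foraging to
design experiments against or to compare with data.

## Worked example

Solve the intermediate reference environment, run a 20000-time-unit
session with patch-to-patch density variation, and compare the
residence-time adjustment with the first-order prediction:

```r
library(forageDDM)

sol <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)
sol
#> MVT solution (A = 5, T_tr = 5, s = 1):
#>   rho0 = 9.4386   E* = 2.0000   T* = 5.7310

env <- environment_spec(rho0 = sol$rho0, rho0_sd = 0.3 * sol$rho0,
                        A = 5, t_travel = 5)
st  <- strategy_params("density_adaptive", sol$rho0, 5,
                       E = sol$E_star, s = 1)
ses <- simulate_session(env, st, cfg = sde_config(sigma = 0.3 * sol$rho0),
                        seed = 1)
ses
#> Foraging session (density_adaptive strategy, 1791 patches in window):
#>   energy rate 2.0128 (sd 0.8727)   PRT 5.6020 (sd 1.6054)

fit <- prt_regression(ses$visits)
round(c(slope = fit$slope, se = fit$stderr), 3)
#>  slope     se
#>  0.419  0.009
prt_sensitivity_density(st$alpha, sol$rho0, 5, 2, 1)$dT_drho0
#> [1] 0.5297407
```

Reading the numbers: a patch density of 9.439 is exactly what makes an
average net rate of 2 self-consistent in this geometry, with an optimal
stay of 5.73 time units.  The noisy forager realizes a net rate of 2.01 —
essentially optimal — with mean residence 5.60, slightly below `T*`
because the energy estimate runs a little hot at patch exits.  The forager
stays about 0.42 time units longer per unit of extra patch density; the
first-order prediction for a fixed-threshold forager is 0.53, and the gap
closes as the decision noise and the coupling of the threshold to the
running estimate are switched off (see the tests).

The same machinery is scriptable from a shell:

```sh
Rscript inst/exec/forageddm mvt --preset medium-default
Rscript inst/exec/forageddm simulate --preset medium-default --seed 1 --out-dir out/
```

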