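---
title: "An evidence-accumulation model of patch-leaving decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An evidence-accumulation model of patch-leaving decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forageDDM)
```

## The model

A forager alternates between exploiting depletable food patches and
traveling between them.  `forageDDM` describes its decisions with two
coupled stochastic processes.

**Energy estimate.**  The net rate of energy gain is `r(t) - s` inside a
patch and `-s` while traveling, where `r(t)` is the reward stream and `s`
a constant cost.  The forager tracks the environment with an exponential
moving average

$$\tau_E \, dE = (r(t) - s - E)\, dt,$$

so `E` relaxes toward the recent net intake rate with timescale
$\tau_E$.

**Patch decision variable.**  Within a patch, a drift-diffusion
accumulator `x` starts at zero on entry and the forager leaves when `x`
reaches a threshold $\eta$:

$$\tau \, dx = (\alpha - r(t))\, dt + \sigma\, dW(t).$$

**Patch depletion.**  Food sits in a patch of size `A` (in time units;
the search rate is fixed at one unit area per unit time, so patch area
and `A` coincide numerically) in chunks of size `c`.  The number of
chunks found in a step of length $\Delta t$ is Poisson with rate
$\rho(t)\Delta t / c$, and eating removes the food from the patch, so the
ensemble-mean density decays as $\rho_0 e^{-t/A}$.  The limit `c = 0` is
continuous reward at exactly that rate.

**The optimality layer.**  For continuous rewards the marginal value
theorem (MVT) fixes the optimal residence time
$T^* = A \log(\rho_0/(\langle E\rangle + s))$, and the consistency of the
average rate over full patch-plus-travel cycles with $T^*$ determines
$\rho_0$ given the target rate (or vice versa); `solve_environment()`
solves this pair by bracketed root-finding (the objective is monotone on
the feasible interval, so Brent's method with a grown bracket cannot
miss).  Integrating the noiseless accumulator up to $T^*$ ties the
threshold to the drift,

$$\eta = A\big(\alpha \log \tfrac{\rho_0}{E+s} - \rho_0 + E + s\big),$$

which makes *any* drift on the valid branches exactly MVT-equivalent in
the limit of frozen `E`, zero noise and continuous reward.  The named
strategies are particular drift choices: density-adaptive
($\alpha = \bar\rho_0$), size-adaptive (threshold exactly zero), counting
($\alpha = 0$) and robust counting ($\alpha = c_{rc}\bar\rho_0$ with
$c_{rc} = -0.2$ by default).  Drifts between $E+s$ and the size-adaptive
value produce a double threshold crossing and are flagged invalid by
`drift_validity()`.

**Satisficing utility.**  A marginal utility that declines with the
energy estimate modulates the dynamics,

$$\tau\, dx = \big(\alpha\, u(E) - r(t)\, u(E)^{-\mathrm{sgn}(\eta)}\big) dt
  + \sigma\, dW(t),$$

so a well-fed forager both drifts toward the leave threshold more slowly
and weighs food in the direction of staying.  The exponent's sign makes
this work on both branches: with a positive threshold food pushes *away*
from leaving, and dividing by `u < 1` amplifies that push; with a
negative threshold food pushes *toward* leaving, and multiplying by `u`
attenuates it.  We resolve the typographic ambiguity of the published
form this way because it is the only reading consistent with the verbal
contract that utility lengthens stays on both branches; `sgn(0)` is taken
as `+1`.  Two marginal utility forms are provided (exponential and
threshold-linear), both with `u(0) = 1` and a floor; the utility argument
is clamped at zero from below, since a forager running at a loss has no
reason to discount food.

## Parameters, units, defaults

Time is measured in units of the decision timescale $\tau$ and energy in
units of the cost `s`, so the defaults are $\tau = 1$, `s = 1`.  The
figure-caption statement of the cost in the source material is internally
inconsistent with its own derived numbers; `s = 1` with a target rate of
2 reproduces both the printed density 9.439 and the printed chunk count
4.02, so that convention is adopted throughout.

| parameter | meaning | default | why |
|---|---|---|---|
| `tau_E` | energy-averaging timescale | `50 tau` | estimate evolves slower than single patch decisions |
| `dt` | Euler-Maruyama step | `0.01 tau` | the stated simulation step of the study conditions |
| `total_time` | session length | `20000 tau` | long enough for ~2000 cycles |
| `burn_in` | discarded transient | `1000 tau` | removes the `E`-initialization transient |
| `sigma` | decision noise | 0 (set per experiment) | study conditions use up to `0.3 rho0` |
| `rho0_sd` | patch density spread | 0 (set per experiment) | uncertain-density condition uses `0.3 rho0_bar` |
| `rc_scale` | robust-counting drift multiplier | `-0.2` | the study's robust-counting setting |

The measurement window starts at the first patch entry at or after the
burn-in and ends with the last *complete* patch-plus-travel cycle before
the session end, so windowed sums of residence and travel tile the window
exactly and the realized net rate is a true time average.  The summary
reports both that realized rate (what the MVT optimizes) and the
forager's own estimate at patch exits; the two converge in steady state.

## What the generator emulates — and what it does not

The synthetic environment reproduces the study conditions: fixed or
Gaussian patch density and size (Gaussian draws resampled until positive,
which at the standard spread of 30% of the mean alters well under 0.1% of
draws), fixed or exponential travel times, Poisson chunk arrivals with
exponential mean depletion, and a constant cost.  It does **not** emulate
spatial structure, temporally autocorrelated or non-stationary
environments, patch-type recognition on entry, competition, or learning
of the environment means — the forager is *given* $\bar\rho_0$ and
$\bar A$.  Passing tests therefore demonstrate internal consistency of
the model and its analytics under these idealized conditions, not that
real foraging data will follow them.

## Numerical choices

- **Crossing detection** happens at step ends with no sub-step
  interpolation, matching the stated stepper of the study conditions;
  `dt = 0.01 tau` bounds the bias at about half a step.  The noiseless
  session tests assert leaving within one step of $T^*$.
- **Seed contract**: a session is a pure function of (configuration,
  seed).  The compiled loop consumes the R RNG stream in exactly the
  order of the exported single-step functions, and a parity test holds
  the two bit-equal.  Sweep replicates derive their seeds as
  `base_seed + (cell-1)*replicates + (replicate-1)`.
- **Food delivery is capped** at the food remaining in the patch, so
  total extraction can never exceed `A rho0` (the Poisson draw alone
  would occasionally overdraw an almost-empty patch).
- **Degenerate exits**: if the running estimate reaches
  `rho0_bar - s` the threshold relation is undefined — the forager
  believes no patch is worth entering — and the patch is left
  immediately; such exits are counted and reported.  They do not occur
  under the study conditions.
- **Threshold updating**: the threshold (and the size-adaptive drift) is
  recomputed every step from the running estimate, which is what makes
  the within-patch threshold collapse visible in example trajectories;
  per-patch freezing is available as a flag (`update_each_step = FALSE`)
  since the original simulations do not state which was used.
- **Fokker-Planck solver**: Crank-Nicolson central differences on a
  uniform grid, absorbing condition at the threshold.  The far boundary
  is also absorbing but placed far enough that the mass reaching it
  (monitored by a flux integral) stays below `1e-8`; this makes the
  probability balance survival + absorbed + leak = 1 exact by
  construction, while the leak bound and an independent flux-integral
  cross-check of the absorbed mass are real numerical diagnostics.  The
  solve refuses to run when the cell Peclet number exceeds 2 and the
  error message says how to refine.  The delta initial condition is a
  Gaussian at least two cells wide.  Against the inverse-Gaussian closed
  form the default resolution achieves a Kolmogorov-Smirnov distance
  below $10^{-4}$.
- **Monte-Carlo cross-validation** of the solver runs the trajectory arm
  at `dt = 0.001`, because discrete-time crossing detection biases
  first-passage times upward by $O(\sigma\sqrt{dt})$ and at the default
  step that bias would be comparable to the two-standard-error
  comparison band.
- **Counting overshoot**: the food collected by a zero-drift forager at
  leaving lies in $[|\eta|\tau, |\eta|\tau + c]$ — the overshoot is at
  most one chunk — as a property of the continuous-time process.  A
  single Euler step can deliver two chunks at once (the Poisson draw is
  not truncated), so the property test runs at `dt = 5e-4` where
  multi-chunk steps are negligible.
- **Utility fixed point**: the deterministic self-consistent
  (energy, residence) pair is found by damped fixed-point iteration
  (damping 0.5, absolute tolerance `1e-8`) between the utility-modified
  noiseless crossing time and the full-cycle average rate.  With zero
  drift and a strong utility the crossing time can be genuinely infinite
  (the discounted food never reaches the threshold); this is reported as
  an error rather than hidden, and is why the decremental branch is
  explored with robust counting.
- **Truncated root brackets**: all root-finding is bracketed and the
  brackets grown geometrically, with hard caps that turn silent failures
  into errors.

## Problem sizes

The test suite runs full sessions of 3000-5000 time units (hundreds of
cycles) with three seeds per stochastic claim, Monte-Carlo samples of
$10^4$ trajectories for distribution-level checks, and Fokker-Planck
grids of 1000-2000 spatial points; these sizes give comfortable margins
for every assertion while keeping the default suite around half a
minute.  A full 20000-time-unit session takes well under a second, so
users can scale any of these up freely.

## Known limitations

- The energy-coupled threshold makes the first-passage problem a
  moving-boundary problem; the solver treats the boundary as fixed
  during a solve (the single-patch, frozen-estimate setting) and does
  not solve the joint `(x, E)` density.
- MVT baselines in heterogeneous environments use the mean patch
  parameters; the exact optimal-energy calculation for environments
  whose patches vary in quality is out of scope.
- The mean residence time of free-running noisy sessions sits slightly
  below $T^*$ — a real feature of the finite `tau_E` coupling, not a
  discretization artifact — so comparisons against the analytics layer
  should use the frozen-estimate mode.
- Leaky (Ornstein-Uhlenbeck) accumulation, multi-patch memory, learning
  of the environment parameters and multi-agent foraging are not
  modelled.
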