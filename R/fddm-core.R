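#' Integration settings for the coupled stochastic system
#'
#' @param tau decision timescale (the unit of time; default 1).
#' @param tau_E timescale of the energy moving average (default `50 * tau`:
#'   the environment estimate evolves much more slowly than individual
#'   patch decisions).
#' @param sigma noise amplitude on the decision variable (>= 0).
#' @param dt Euler-Maruyama step (default `0.01 * tau`).
#' @param seed optional RNG seed recorded with the configuration.
#' @return An object of class `sde_config`.
#' @export
sde_config <- function(tau = 1, tau_E = 50 * tau, sigma = 0, dt = 0.01 * tau,
                       seed = NULL) {
  stopifnot(tau > 0, tau_E > 0, sigma >= 0, dt > 0)
  structure(list(tau = tau, tau_E = tau_E, sigma = sigma, dt = dt, seed = seed),
            class = "sde_config")
}

#' Satisficing marginal utility of additional food
#'
#' The marginal utility declines with the estimated energy rate `E`:
#' when food is plentiful the forager cares less about maximizing
#' intake.  `u(0) = 1` always; `u` is non-increasing in `E` and bounded
#' below by `floor`.
#'
#' @param form `"none"` (utility identically 1), `"exponential"`
#'   (`(1 - floor) exp(-beta E) + floor`) or `"threshold_linear"`
#'   (`max(1 - beta E, floor)`).
#' @param beta decay rate of utility with energy (>= 0).
#' @param floor lower asymptote/floor in `[0, 1]`.
#' @return An object of class `utility_config`.
#' @export
utility_config <- function(form = c("none", "exponential", "threshold_linear"),
                           beta = 0, floor = 0) {
  form <- match.arg(form)
  stopifnot(beta >= 0, floor >= 0, floor <= 1)
  structure(list(form = form, beta = beta, floor = floor),
            class = "utility_config")
}

#' Evaluate the marginal utility at an energy estimate
#'
#' Negative estimates (a forager running at a loss) receive full utility
#' 1: the utility argument is an energy surplus.
#'
#' @param u a [utility_config()].
#' @param E energy estimate (any real; may be a vector).
#' @return Utility value(s) in `[floor, 1]`.
#' @examples
#' utility_value(utility_config("exponential", beta = 1), E = 2)  # exp(-2)
#' @export
utility_value <- function(u, E) {
  stopifnot(inherits(u, "utility_config"))
  e <- pmax(E, 0)
  switch(u$form,
    none = rep(1, length(e)),
    exponential = (1 - u$floor) * exp(-u$beta * e) + u$floor,
    threshold_linear = pmax(1 - u$beta * e, u$floor))
}

#' State of a foraging agent
#'
#' @param x patch decision variable (reset to 0 at each patch entry).
#' @param E estimated net energy rate of the environment.
#' @param phase `"in_patch"` or `"traveling"`.
#' @param t global clock.
#' @param patch the current [patch_state()], or `NULL` while traveling.
#' @param t_phase time spent in the current phase.
#' @return An object of class `forager_state`.
#' @export
forager_state <- function(x = 0, E = 0, phase = c("in_patch", "traveling"),
                          t = 0, patch = NULL, t_phase = 0) {
  phase <- match.arg(phase)
  if (phase == "in_patch") stopifnot(inherits(patch, "patch_state"))
  structure(list(x = x, E = E, phase = phase, t = t, patch = patch,
                 t_phase = t_phase),
            class = "forager_state")
}

#' Current decision threshold given the running energy estimate
#'
#' The threshold is the optimal-threshold relation evaluated at the
#' environment means with the forager's *current* energy estimate in
#' place of the true average, so it moves within a patch as food updates
#' the estimate.  For the size-adaptive strategy the drift itself is
#' also re-evaluated at the current estimate.
#'
#' If the estimate has risen so far that the relation is undefined
#' (`E >= rho0_bar - s`: the forager believes no patch is worth
#' entering), `NA` is returned and callers treat the patch as left
#' immediately (a degenerate exit).
#'
#' @param strategy a [strategy_params()].
#' @param E current energy estimate.
#' @param s constant cost.
#' @return The threshold, or `NA_real_` when undefined.
#' @export
current_threshold <- function(strategy, E, s) {
  stopifnot(inherits(strategy, "strategy_params"))
  if (E + s >= strategy$rho0_bar) return(NA_real_)
  alpha <- if (strategy$kind == "size_adaptive")
    (strategy$rho0_bar - E - s) / log(strategy$rho0_bar / (E + s))
  else strategy$alpha
  optimal_threshold(alpha, strategy$rho0_bar, strategy$A_bar, E, s)
}

#' Has the decision variable crossed the threshold?
#'
#' Crossings are detected at step ends without sub-step interpolation:
#' `x >= eta` for a non-negative threshold, `x <= eta` for a negative
#' one.
#'
#' @param x decision variable value(s).
#' @param eta threshold.
#' @return Logical.
#' @export
crossed <- function(x, eta) {
  if (is.na(eta)) return(TRUE)
  if (eta >= 0) x >= eta else x <= eta
}

#' One Euler-Maruyama step of the in-patch dynamics
#'
#' Draws the food reward for the step, applies the utility-weighted
#' decision update
#' `x <- x + (alpha u dt - food * u^(-sgn(eta)))/tau + (sigma/tau) sqrt(dt) N(0,1)`,
#' relaxes the energy estimate toward the realized net rate, depletes
#' the patch, and advances the clocks.  The threshold (and, for the
#' size-adaptive strategy, the drift) is recomputed from the current
#' energy estimate at the start of the step.
#'
#' This is the reference single-step implementation; full sessions run
#' the identical update in compiled code ([simulate_session()]), and the
#' two produce bit-identical trajectories under the same seed.
#'
#' @param state a [forager_state()] with `phase == "in_patch"`.
#' @param strategy a [strategy_params()].
#' @param u a [utility_config()].
#' @param cfg an [sde_config()].
#' @param env an [environment_spec()] (supplies the cost `s`).
#' @return The updated [forager_state()], with elements `eta` (the
#'   threshold used), `food` (energy received this step) and `crossed`
#'   (logical leave flag) appended.
#' @export
step_in_patch <- function(state, strategy, u, cfg, env) {
  stopifnot(inherits(state, "forager_state"), state$phase == "in_patch")
  eta <- current_threshold(strategy, state$E, env$s)
  if (is.na(eta)) {
    state$eta <- NA_real_; state$food <- 0; state$crossed <- TRUE
    return(state)
  }
  alpha <- if (strategy$kind == "size_adaptive")
    (strategy$rho0_bar - state$E - env$s) / log(strategy$rho0_bar / (state$E + env$s))
  else strategy$alpha
  rw <- sample_reward(state$patch, cfg$dt)
  z <- if (cfg$sigma > 0) rnorm(1L) else 0
  uval <- utility_value(u, state$E)
  sgn <- if (eta >= 0) 1 else -1
  state$x <- state$x +
    (alpha * uval * cfg$dt - rw$food * uval^(-sgn)) / cfg$tau +
    (cfg$sigma / cfg$tau) * sqrt(cfg$dt) * z
  state$E <- state$E + cfg$dt * (-env$s - state$E) / cfg$tau_E + rw$food / cfg$tau_E
  state$patch <- deplete(state$patch, rw$food)
  state$patch$t_in <- state$patch$t_in + cfg$dt
  state$t <- state$t + cfg$dt
  state$t_phase <- state$t_phase + cfg$dt
  state$eta <- eta
  state$food <- rw$food
  state$crossed <- crossed(state$x, eta)
  state
}

#' One step of the between-patch (travel) dynamics
#'
#' While traveling the reward rate is zero, so the energy estimate
#' relaxes exponentially toward `-s`; the decision variable is held at
#' zero.
#'
#' @param state a [forager_state()] with `phase == "traveling"`.
#' @param cfg an [sde_config()].
#' @param env an [environment_spec()].
#' @param dt step length; defaults to `cfg$dt` (the final step of a
#'   travel leg is shortened to land exactly on the drawn travel time).
#' @return The updated [forager_state()].
#' @export
step_travel <- function(state, cfg, env, dt = cfg$dt) {
  stopifnot(inherits(state, "forager_state"), state$phase == "traveling")
  state$E <- state$E + dt * (-env$s - state$E) / cfg$tau_E
  state$x <- 0
  state$t <- state$t + dt
  state$t_phase <- state$t_phase + dt
  state
}
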