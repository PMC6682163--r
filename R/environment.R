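#' Describe a foraging environment
#'
#' An environment is a statistical description of the patches a forager
#' encounters: the distribution of initial patch food density and patch
#' size, the food chunk size, the distribution of inter-patch travel
#' times, and the constant metabolic cost.  Time is measured in units of
#' the decision timescale `tau` and energy in units of the cost `s`, so
#' the defaults `s = 1`, `tau = 1` are the natural choice.
#'
#' Initial density and patch size are either fixed (`rho0_sd = 0`,
#' `A_sd = 0`) or Gaussian with the given mean and standard deviation;
#' Gaussian draws are resampled until positive.  Travel times are either
#' fixed or exponential with mean `t_travel`.
#'
#' @param rho0 mean initial food density (energy per unit time at patch
#'   entry; the search rate is fixed at 1).
#' @param A mean patch size, in time units (`A = a/v` with search rate
#'   `v = 1`, so patch area equals `A` numerically).
#' @param rho0_sd,A_sd standard deviations for Gaussian patch-to-patch
#'   variation; 0 means every patch is identical.
#' @param c food chunk size in energy units; `c = 0` is the continuous
#'   reward limit.
#' @param t_travel mean travel time between patches.
#' @param travel `"fixed"` (every travel takes exactly `t_travel`) or
#'   `"exponential"` (exponential with mean `t_travel`).
#' @param s constant cost, energy per unit time.
#' @return An object of class `environment_spec`.
#' @examples
#' env <- environment_spec(rho0 = 9.439, A = 5, t_travel = 5)
#' @export
environment_spec <- function(rho0, A, rho0_sd = 0, A_sd = 0, c = 0,
                             t_travel = 5, travel = c("fixed", "exponential"),
                             s = 1) {
  travel <- match.arg(travel)
  stopifnot(is.numeric(rho0), rho0 > 0, is.numeric(A), A > 0,
            rho0_sd >= 0, A_sd >= 0, c >= 0, t_travel > 0, s > 0)
  structure(list(rho0 = rho0, rho0_sd = rho0_sd, A = A, A_sd = A_sd,
                 c = c, t_travel = t_travel, travel = travel, s = s),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  d <- function(m, s) if (s > 0) sprintf("N(%g, %g)", m, s) else sprintf("%g", m)
  cat("Foraging environment:\n",
      "  rho0: ", d(x$rho0, x$rho0_sd), "   A: ", d(x$A, x$A_sd), "\n",
      "  chunk size c: ", x$c, "   cost s: ", x$s, "\n",
      "  travel: ", if (x$travel == "exponential")
        sprintf("Exp(mean %g)", x$t_travel) else sprintf("fixed %g", x$t_travel),
      "\n", sep = "")
  invisible(x)
}

#' Parameters of a single patch
#'
#' @param rho0 initial food density (> 0).
#' @param A patch size in time units (> 0).
#' @param c food chunk size (>= 0; 0 = continuous reward).
#' @return An object of class `patch_spec`.
#' @export
patch_spec <- function(rho0, A, c = 0) {
  stopifnot(rho0 > 0, A > 0, c >= 0)
  structure(list(rho0 = rho0, A = A, c = c), class = "patch_spec")
}

#' Current state of a (depleting) patch
#'
#' @param spec a [patch_spec()].
#' @param rho current food density; defaults to `spec$rho0` (a fresh patch).
#' @param t_in time since patch entry.
#' @return An object of class `patch_state`.
#' @export
patch_state <- function(spec, rho = spec$rho0, t_in = 0) {
  stopifnot(inherits(spec, "patch_spec"), rho >= 0, rho <= spec$rho0 + 1e-12,
            t_in >= 0)
  structure(list(spec = spec, rho = rho, t_in = t_in), class = "patch_state")
}

# Gaussian draw truncated to (0, Inf) by resampling; errors after 1000
# failures, which signals a pathological sd relative to the mean.
.draw_positive <- function(mean, sd, what) {
  if (sd <= 0) return(mean)
  for (i in 1:1000) {
    x <- rnorm(1L, mean, sd)
    if (x > 0) return(x)
  }
  stop(sprintf("could not draw a positive %s after 1000 attempts (mean = %g, sd = %g)",
               what, mean, sd))
}

#' Draw a fresh patch from an environment
#'
#' Initial density and size are drawn from the configured distributions
#' (Gaussian draws resampled until positive) and the patch starts full.
#'
#' @param env an [environment_spec()].
#' @return A [patch_state()] with `rho = rho0` and `t_in = 0`.
#' @export
draw_patch <- function(env) {
  stopifnot(inherits(env, "environment_spec"))
  rho0 <- .draw_positive(env$rho0, env$rho0_sd, "patch density")
  A <- .draw_positive(env$A, env$A_sd, "patch size")
  patch_state(patch_spec(rho0, A, env$c))
}

#' Draw an inter-patch travel time
#'
#' @param env an [environment_spec()].
#' @return A positive duration: the constant `t_travel` in fixed mode, or
#'   an exponential draw with that mean.
#' @export
draw_travel_time <- function(env) {
  stopifnot(inherits(env, "environment_spec"))
  if (env$travel == "exponential") rexp(1L, rate = 1 / env$t_travel)
  else env$t_travel
}

#' Sample the food reward received in one time step
#'
#' With chunked food (`c > 0`) the number of chunks found in `dt` is
#' Poisson with rate `rho * dt / c`; with `c = 0` the reward is the
#' continuous limit `rho * dt`.  In both modes the expected reward is
#' `rho * dt`.  Delivered food is capped at the food remaining in the
#' patch (`rho * A`) so that total extraction can never exceed the
#' initial patch content `A * rho0`.
#'
#' @param state a [patch_state()].
#' @param dt step duration (> 0).
#' @return A list with `k` (chunk count; 0 in continuous mode) and `food`
#'   (energy obtained).
#' @export
sample_reward <- function(state, dt) {
  stopifnot(inherits(state, "patch_state"), dt > 0)
  c <- state$spec$c
  if (c > 0) {
    k <- rpois(1L, state$rho * dt / c)
    food <- min(k * c, state$rho * state$spec$A)
    list(k = k, food = food)
  } else {
    list(k = 0L, food = state$rho * dt)
  }
}

#' Deplete a patch by the food just eaten
#'
#' Eating `food` removes `food / A` from the density (patch area equals
#' `A` with unit search rate); the density is floored at zero.
#'
#' @param state a [patch_state()].
#' @param food energy eaten (>= 0).
#' @return The updated [patch_state()] (the in-patch clock is advanced by
#'   the stepping routines, not here).
#' @export
deplete <- function(state, food) {
  stopifnot(inherits(state, "patch_state"), food >= 0)
  state$rho <- max(0, state$rho - food / state$spec$A)
  state
}

#' Expected food density after a residence time
#'
#' The ensemble-mean density decays exponentially with the time spent in
#' the patch: `rho0 * exp(-t / A)`.
#'
#' @param spec a [patch_spec()].
#' @param t time since patch entry (>= 0); may be a vector.
#' @return Expected density at `t`.
#' @export
mean_density <- function(spec, t) {
  stopifnot(inherits(spec, "patch_spec"), all(t >= 0))
  spec$rho0 * exp(-t / spec$A)
}
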