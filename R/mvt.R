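#' Marginal-value-theorem optimal patch residence time
#'
#' For exponentially depleting patches the marginal value theorem gives
#' the optimal residence time in closed form,
#' \deqn{T^* = A \log(\rho_0 / (\langle E\rangle + s)),}
#' the time at which the instantaneous net intake rate
#' `rho0 * exp(-t/A) - s` has fallen to the average net rate `E`.
#'
#' @param rho0 initial patch food density.
#' @param A patch size (time units).
#' @param E average net energy rate from the environment.
#' @param s constant cost.
#' @return The optimal residence time (> 0 requires `rho0 > E + s`).
#' @examples
#' optimal_patch_time(9.439, A = 5, E = 2, s = 1)  # ~5.731
#' @export
optimal_patch_time <- function(rho0, A, E, s) {
  stopifnot(A > 0, s > 0)
  if (rho0 < E + s) stop("rho0 must exceed E + s: the patch never pays for staying")
  A * log(rho0 / (E + s))
}

#' Solve an environment for its MVT-consistent density or energy rate
#'
#' The MVT self-consistency conditions couple the average net rate
#' `E` over full patch + travel cycles with the optimal residence time:
#' leave when the marginal rate equals the average rate, i.e.
#' `(E + s) (T_tr + T*) = A (rho0 - E - s)` with
#' `T* = A log(rho0/(E+s))`.  Given the environment geometry and one of
#' `rho0` or `E_star`, this solves for the other by bracketed
#' root-finding (the objective is monotone on the feasible interval).
#'
#' @param A patch size.
#' @param T_tr travel time between patches (its mean, if stochastic).
#' @param s constant cost.
#' @param rho0 initial patch density (supply this *or* `E_star`).
#' @param E_star target MVT-optimal average net energy rate.
#' @param tol relative root tolerance.
#' @return An object of class `mvt_solution`: a list with `rho0`,
#'   `E_star`, `T_star`, `A`, `T_tr`, `s`.
#' @examples
#' solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)  # rho0 = 9.439
#' @export
solve_environment <- function(A, T_tr, s, rho0 = NULL, E_star = NULL,
                              tol = 1e-10) {
  stopifnot(A > 0, T_tr > 0, s > 0)
  if (is.null(rho0) == is.null(E_star))
    stop("supply exactly one of rho0 or E_star")
  cycle_gap <- function(r, E)   # >0 when patches are richer than consistency requires
    A * (r - E - s) - (E + s) * (T_tr + A * log(r / (E + s)))
  if (is.null(rho0)) {
    E <- E_star
    if (E + s <= 0) stop("E_star + s must be positive: no feasible density exists")
    lo <- (E + s) * (1 + 1e-12); hi <- (E + s) + 1
    while (cycle_gap(hi, E) < 0) {
      hi <- hi * 2
      if (hi > 1e12) stop("no root found for rho0")
    }
    rho0 <- uniroot(cycle_gap, c(lo, hi), E = E, tol = tol * (E + s))$root
  } else {
    if (rho0 <= s) stop("rho0 <= s: even an undepleted patch cannot pay the cost")
    # E is bracketed by (-s, rho0 - s); gap is decreasing in E
    lo <- -s + 1e-12; hi <- rho0 - s - 1e-12
    E_star <- uniroot(function(E) cycle_gap(rho0, E), c(lo, hi),
                      tol = tol * max(1, rho0))$root
  }
  structure(list(rho0 = rho0, E_star = E_star,
                 T_star = optimal_patch_time(rho0, A, E_star, s),
                 A = A, T_tr = T_tr, s = s),
            class = "mvt_solution")
}

#' @export
print.mvt_solution <- function(x, ...) {
  cat(sprintf(
    "MVT solution (A = %g, T_tr = %g, s = %g):\n  rho0 = %.4f   E* = %.4f   T* = %.4f\n",
    x$A, x$T_tr, x$s, x$rho0, x$E_star, x$T_star))
  invisible(x)
}

#' Optimal decision threshold for a given drift rate
#'
#' Integrating the noiseless decision variable with the mean reward
#' stream up to the MVT-optimal residence time ties the threshold to the
#' drift rate:
#' \deqn{\eta = A(\alpha \log(\rho_0/(E+s)) - \rho_0 + E + s).}
#' At run time foragers substitute their *current* energy estimate for
#' `E`, which makes the threshold collapse as the estimate rises.
#'
#' @param alpha drift rate of the decision variable.
#' @inheritParams optimal_patch_time
#' @return The threshold `eta` (same sign as `alpha` on each valid branch;
#'   negative for `alpha = 0`).
#' @export
optimal_threshold <- function(alpha, rho0, A, E, s) {
  stopifnot(A > 0, s > 0)
  if (rho0 <= E + s) stop("threshold undefined: rho0 must exceed E + s")
  A * (alpha * log(rho0 / (E + s)) - rho0 + E + s)
}

#' Named patch-leaving strategies
#'
#' A strategy is a rule for the drift rate of the decision variable,
#' with the threshold tied to it by [optimal_threshold()]:
#' \describe{
#'   \item{density_adaptive}{`alpha = rho0_bar`; food opposes a positive
#'     drift (increment-decrement mechanism), and residence times adapt
#'     optimally to patch-to-patch variation in food density.}
#'   \item{size_adaptive}{`alpha = (rho0_bar - E - s)/log(rho0_bar/(E+s))`,
#'     giving a threshold of exactly zero; adapts residence to patch-size
#'     variation but is maximally noise-sensitive.}
#'   \item{counting}{`alpha = 0`; the forager leaves after a set amount of
#'     food (decremental mechanism).}
#'   \item{robust_counting}{`alpha = rc_scale * rho0_bar` with
#'     `rc_scale < 0`, so the forager still drifts toward the (negative)
#'     threshold when no food arrives.}
#' }
#'
#' @param kind one of `"density_adaptive"`, `"size_adaptive"`,
#'   `"counting"`, `"robust_counting"`.
#' @param rho0_bar,A_bar mean initial density and mean patch size the
#'   forager assumes for the environment.
#' @param E energy rate at which to evaluate the threshold (typically the
#'   running estimate, or the MVT value for analysis).
#' @param s constant cost.
#' @param rc_scale drift multiplier for robust counting (must be < 0;
#'   default -0.2, i.e. `alpha = -0.2 rho0_bar`).
#' @return An object of class `strategy_params` with fields `kind`,
#'   `alpha`, `eta`, `rho0_bar`, `A_bar`, `rc_scale`.
#' @examples
#' strategy_params("density_adaptive", 9.439, 5, E = 2, s = 1)
#' @export
strategy_params <- function(kind = c("density_adaptive", "size_adaptive",
                                     "counting", "robust_counting"),
                            rho0_bar, A_bar, E, s, rc_scale = -0.2) {
  kind <- match.arg(kind)
  stopifnot(rho0_bar > E + s)
  if (kind == "robust_counting" && rc_scale >= 0)
    stop("robust_counting requires rc_scale < 0")
  alpha <- switch(kind,
    density_adaptive = rho0_bar,
    size_adaptive = (rho0_bar - E - s) / log(rho0_bar / (E + s)),
    counting = 0,
    robust_counting = rc_scale * rho0_bar)
  structure(list(kind = kind, alpha = alpha,
                 eta = optimal_threshold(alpha, rho0_bar, A_bar, E, s),
                 rho0_bar = rho0_bar, A_bar = A_bar, rc_scale = rc_scale),
            class = "strategy_params")
}

#' @export
print.strategy_params <- function(x, ...) {
  cat(sprintf("strategy %s: alpha = %.4f, eta = %.4f (rho0_bar = %g, A_bar = %g)\n",
              x$kind, x$alpha, x$eta, x$rho0_bar, x$A_bar))
  invisible(x)
}

#' Validity range of the drift rate
#'
#' Between `alpha_crit = E + s` and the size-adaptive drift `alpha_S`
#' the noiseless decision variable crosses its threshold twice (once
#' early, once at the optimal time), so a simulation would need an extra
#' rule to ignore the first crossing; the band `0 < alpha < alpha_crit`
#' is additionally excluded because drift and threshold have opposite
#' signs there.  Valid drifts are `alpha <= 0` (decremental branch) or
#' `alpha >= alpha_S` (increment-decrement branch).
#'
#' @inheritParams optimal_threshold
#' @return A list with `alpha_crit`, `alpha_S`, and logical `valid`.
#' @export
drift_validity <- function(alpha, rho0, A, E, s) {
  stopifnot(rho0 > E + s)
  alpha_S <- (rho0 - E - s) / log(rho0 / (E + s))
  list(alpha_crit = E + s, alpha_S = alpha_S,
       valid = alpha <= 0 | alpha >= alpha_S)
}

#' Expected number of food chunks per patch under the optimal policy
#'
#' With discrete chunks of size `c`, the food an optimal forager extracts
#' per patch, `A (rho0 - E - s)`, corresponds to
#' \deqn{N_{opt} = (A/c)(\rho_0 - E - s)} chunks.
#'
#' @inheritParams optimal_patch_time
#' @param c chunk size (> 0).
#' @export
n_opt <- function(rho0, A, c, E, s) {
  if (c <= 0) stop("n_opt requires a positive chunk size")
  stopifnot(rho0 > E + s)
  (A / c) * (rho0 - E - s)
}

#' First-order residence-time sensitivity to patch density
#'
#' Under a fixed strategy `(alpha, eta)` set from the environment means,
#' the noiseless leaving time of a patch whose initial density deviates
#' by `delta rho0` from the mean shifts, to first order, by
#' `dT_drho0 * delta rho0` with
#' \deqn{dT/d\rho_0 = \bar A (E + s - \bar\rho_0) / (\bar\rho_0 (E + s - \alpha)).}
#' At `alpha = rho0_bar` this reduces to the MVT-optimal adjustment
#' `A_bar / rho0_bar`; for decremental strategies (`alpha <= 0`) the
#' slope is negative: such foragers leave richer patches *sooner*.
#'
#' @param alpha drift rate (must differ from `E + s`).
#' @param rho0_bar,A_bar environment means.
#' @param E,s energy rate and cost.
#' @return A list with `dT_drho0`.
#' @export
prt_sensitivity_density <- function(alpha, rho0_bar, A_bar, E, s) {
  stopifnot(rho0_bar > E + s)
  if (abs(alpha - (E + s)) < 1e-12)
    stop("sensitivity is singular at alpha = E + s (the critical drift)")
  list(dT_drho0 = A_bar * (E + s - rho0_bar) / (rho0_bar * (E + s - alpha)))
}

#' First-order residence-time sensitivity to patch size
#'
#' Analogue of [prt_sensitivity_density()] for patches whose size
#' deviates from the mean:
#' \deqn{dT/dA = [(E+s)(\log(\bar\rho_0/(E+s)) + 1) - \bar\rho_0] / (E + s - \alpha).}
#' At the size-adaptive drift this reduces to the MVT-optimal adjustment
#' `log(rho0_bar/(E+s))`.
#'
#' @inheritParams prt_sensitivity_density
#' @return A list with `dT_dA`.
#' @export
prt_sensitivity_size <- function(alpha, rho0_bar, E, s) {
  stopifnot(rho0_bar > E + s)
  if (abs(alpha - (E + s)) < 1e-12)
    stop("sensitivity is singular at alpha = E + s (the critical drift)")
  L <- log(rho0_bar / (E + s))
  list(dT_dA = ((E + s) * (L + 1) - rho0_bar) / (E + s - alpha))
}

# First crossing time of the noiseless decision variable
#   x(T) = a T - b rho0 A (1 - exp(-T/A))
# with threshold eta: for eta >= 0 the crossing on the rising branch
# (after the minimum of x), for eta < 0 the first downward crossing.
# Returns Inf when the zero-drift trajectory saturates above a negative
# threshold (a counting forager in a patch that never delivers enough).
.det_crossing <- function(a, b, rho0, A, eta, tol = 1e-12) {
  f <- function(T) a * T - b * rho0 * A * (1 - exp(-T / A)) - eta
  if (eta >= 0) {
    if (a <= 0) stop("no upward crossing: non-positive drift with a positive threshold")
    t_lo <- if (a < b * rho0) A * log(b * rho0 / a) else 0
    hi <- max(t_lo, A)
    for (i in 1:200) {
      if (f(hi) > 0) break
      hi <- hi * 2
    }
    if (f(hi) <= 0) stop("no threshold crossing found")
    if (t_lo == 0 && abs(f(0)) < tol) return(0)
    uniroot(f, c(t_lo, hi), tol = tol)$root
  } else {
    if (a > 0) stop("positive drift with a negative threshold: invalid strategy band")
    if (a == 0 && b * rho0 * A <= -eta) return(Inf)
    hi <- A
    for (i in 1:200) {
      if (f(hi) < 0) break
      hi <- hi * 2
    }
    if (f(hi) >= 0) return(Inf)
    uniroot(f, c(0, hi), tol = tol)$root
  }
}

#' Noiseless leaving time under a fixed drift and threshold
#'
#' Integrates the decision variable with the mean reward stream
#' `rho0 exp(-t/A)` and zero noise, and returns the first time the
#' threshold is reached.  This is the deterministic backbone used by the
#' sensitivity predictions: evaluated at the environment means it equals
#' the MVT-optimal residence time whenever `(alpha, eta)` satisfy the
#' optimal-threshold relation.
#'
#' @param alpha drift rate.
#' @param eta threshold.
#' @param rho0,A parameters of the patch actually being exploited.
#' @return The crossing time (possibly `Inf` for a pure counting forager
#'   in a patch that cannot deliver `|eta|` worth of food).
#' @export
deterministic_prt <- function(alpha, eta, rho0, A) {
  stopifnot(rho0 > 0, A > 0)
  .det_crossing(alpha, 1, rho0, A, eta)
}

#' Self-consistent energy and residence time under a marginal utility
#'
#' With a satisficing marginal utility `u(E)` the noiseless decision
#' dynamics become `tau dx = (alpha u - r(t) u^{-sgn(eta)}) dt`, so the
#' leaving time of a patch depends on the energy estimate both through
#' the threshold and through the utility.  This routine solves the
#' coupled deterministic system
#' (i) `T(E)`: leaving time from the utility-modified dynamics at fixed
#' `E`, and (ii) `E(T)`: average net rate over a full cycle of residence
#' `T` plus travel `T_tr`, by damped fixed-point iteration.  With
#' `beta = 0` it recovers the MVT solution exactly; with `beta > 0` the
#' forager stays longer than optimal, the more so the richer the
#' environment.
#'
#' @param kind strategy name as in [strategy_params()].
#' @param utility a [utility_config()].
#' @param A,T_tr,s environment geometry and cost.
#' @param rho0 initial patch density (the environment mean).
#' @param rc_scale robust-counting drift multiplier.
#' @param tol absolute tolerance on the energy fixed point.
#' @param max_iter iteration cap.
#' @param damping step fraction toward the new iterate (0 < damping <= 1).
#' @return A list with the self-consistent `E` and `T`, the MVT reference
#'   `E_star` and `T_star`, and `iterations`/`converged`.
#' @export
utility_fixed_point <- function(kind, utility, A, T_tr, s, rho0,
                                rc_scale = -0.2, tol = 1e-8,
                                max_iter = 1000, damping = 0.5) {
  stopifnot(inherits(utility, "utility_config"), damping > 0, damping <= 1)
  mvt <- solve_environment(A = A, T_tr = T_tr, s = s, rho0 = rho0)
  E <- mvt$E_star
  T_of_E <- function(E) {
    st <- strategy_params(kind, rho0_bar = rho0, A_bar = A, E = E, s = s,
                          rc_scale = rc_scale)
    u <- utility_value(utility, E)
    sgn <- if (st$eta >= 0) 1 else -1
    .det_crossing(st$alpha * u, u^(-sgn), rho0, A, st$eta)
  }
  E_of_T <- function(T)
    (A * rho0 * (1 - exp(-T / A)) - s * (T_tr + T)) / (T_tr + T)
  T <- NA_real_; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    T <- T_of_E(E)
    if (!is.finite(T)) stop("utility fixed point: infinite residence time")
    E_new <- E_of_T(T)
    if (abs(E_new - E) < tol) { converged <- TRUE; E <- E_new; break }
    E <- (1 - damping) * E + damping * E_new
  }
  if (!converged)
    stop(sprintf("utility fixed point did not converge in %d iterations", max_iter))
  list(E = E, T = T_of_E(E), E_star = mvt$E_star, T_star = mvt$T_star,
       iterations = it, converged = converged)
}
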