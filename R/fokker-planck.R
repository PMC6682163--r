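#' Define a first-passage problem for the patch decision variable
#'
#' Between food-driven jumps the decision variable obeys a
#' drift-diffusion equation whose probability density follows the
#' Fokker-Planck equation
#' \deqn{\partial_t p = -v(t)\,\partial_x p + D\,\partial_x^2 p,}
#' with drift `v(t) = (alpha - <r(t)>)/tau` (the mean reward stream
#' stands in for the stochastic one) and diffusion
#' `D = sigma^2 / (2 tau^2)`.  The threshold `eta` is an absorbing
#' boundary; the probability absorbed by time `t` is the probability
#' that the forager has left the patch.
#'
#' @param drift_fn function of time returning the drift `v(t)` (vectorized).
#' @param sigma noise amplitude on the decision variable (> 0).
#' @param tau decision timescale.
#' @param eta absorbing threshold (non-zero; the sign selects the
#'   incremental or decremental branch).
#' @param x_far far boundary, on the opposite side of `x = 0` from
#'   `eta` and far enough away that essentially no mass reaches it (the
#'   leak is monitored during the solve).  Default `-8 |eta|` (sign
#'   flipped for negative thresholds).
#' @param nx number of spatial grid points.
#' @param dt_fp time step of the Crank-Nicolson propagation.
#' @param x0_width standard deviation of the initial Gaussian
#'   approximating the delta at `x = 0`; widened to two grid cells if
#'   smaller.
#' @return An object of class `fp_problem`.
#' @export
fp_problem <- function(drift_fn, sigma, tau = 1, eta, x_far = NULL,
                       nx = 2000, dt_fp = 0.002, x0_width = 0) {
  stopifnot(is.function(drift_fn), sigma > 0, tau > 0, eta != 0,
            nx >= 50, dt_fp > 0, x0_width >= 0)
  if (is.null(x_far)) x_far <- -sign(eta) * 8 * abs(eta)
  if (sign(x_far) == sign(eta) || abs(x_far) <= 0)
    stop("x_far must lie on the opposite side of x = 0 from eta")
  structure(list(drift_fn = drift_fn, sigma = sigma, tau = tau, eta = eta,
                 diffusion = sigma^2 / (2 * tau^2), x_far = x_far, nx = nx,
                 dt_fp = dt_fp, x0_width = x0_width),
            class = "fp_problem")
}

#' Propagate the decision-variable density to the absorbing threshold
#'
#' Crank-Nicolson finite differences with the threshold as an absorbing
#' boundary.  The far boundary also absorbs, but is placed so far away
#' that the mass lost there (monitored by a flux integral and returned
#' as `leak`) stays below ~1e-8; a warning is raised if it does not.
#' The survival curve is the spatial integral of the density; the
#' leave-time density is its negative time derivative; survival plus
#' absorbed mass plus leak account for all probability exactly.
#'
#' The scheme uses central differences, so the solve refuses to run when
#' the cell Peclet number `max|v| dx / (2D)` exceeds 2 (refine `nx` or
#' enlarge the domain).
#'
#' @param problem an [fp_problem()].
#' @param horizon solve duration.
#' @param save_every store a density snapshot every this many steps.
#' @return An object of class `fp_solution`: a list with time grid `t`,
#'   `survival`, `absorbed`, `leak`, leave-time density `f` (at midpoint
#'   times `t_mid`), the spatial grid `x`, density `snapshots` (columns)
#'   with their times `snap_t`, and the problem.
#' @export
solve_density <- function(problem, horizon, save_every = 100L) {
  stopifnot(inherits(problem, "fp_problem"), horizon > 0)
  eta <- problem$eta; D <- problem$diffusion
  flip <- eta < 0    # solve in -x so the absorbing threshold is always on the right
  eta_w <- abs(eta)
  x_far_w <- if (flip) -abs(problem$x_far) else problem$x_far
  nx <- problem$nx; dt <- problem$dt_fp
  x <- seq(x_far_w, eta_w, length.out = nx)
  dx <- x[2] - x[1]
  nt <- ceiling(horizon / dt)
  tg <- seq(0, by = dt, length.out = nt + 1)
  v <- problem$drift_fn(tg)
  if (length(v) == 1) v <- rep(v, nt + 1)
  if (flip) v <- -v
  pe <- max(abs(v)) * dx / (2 * D)
  if (pe > 2)
    stop(sprintf(paste0("cell Peclet number %.2f > 2: central differences would",
                        " be unstable; increase nx (currently %d) or the noise"),
                 pe, nx))
  w <- max(problem$x0_width, 2 * dx)
  p0 <- dnorm(x, 0, w)
  p0[c(1, nx)] <- 0
  p0 <- p0 / (sum(p0) * dx)
  sol <- fp_cn_cpp(v, D, dt, dx, p0, as.integer(save_every))
  surv <- sol$survival
  leak <- sol$leak_cum
  absorbed <- 1 - surv - leak
  if (max(leak) > 1e-8)
    warning(sprintf("far-boundary leak %.2e exceeds 1e-8; move x_far further out",
                    max(leak)))
  f <- -diff(surv) / dt
  snaps <- sol$snapshots
  if (flip) snaps <- snaps[nx:1, , drop = FALSE]
  structure(list(t = tg, survival = surv, absorbed = absorbed, leak = leak,
                 f = f, t_mid = tg[-1] - dt / 2,
                 x = if (flip) rev(-x) else x,
                 snapshots = snaps, snap_t = sol$snap_step * dt,
                 flux_abs = sol$flux_abs, problem = problem),
            class = "fp_solution")
}

#' Moments and quantiles of the patch-leaving time
#'
#' Quadrature over the leave-time density of a [solve_density()]
#' result.  Requires at least 99.9% of the probability to have been
#' absorbed over the solve horizon, otherwise the truncated moments
#' would be biased.
#'
#' @param solution an `fp_solution`.
#' @param probs quantile levels.
#' @return A list with `mean`, `var`, `sd`, `quantiles` and
#'   `absorbed_total`.
#' @export
first_passage_stats <- function(solution, probs = c(0.25, 0.5, 0.75, 0.9)) {
  stopifnot(inherits(solution, "fp_solution"))
  ab <- solution$absorbed[length(solution$absorbed)]
  if (ab < 0.999)
    stop(sprintf("only %.1f%% of the mass absorbed: horizon too short", 100 * ab))
  f <- solution$f; tm <- solution$t_mid; dt <- diff(solution$t[1:2])
  z <- sum(f) * dt
  m1 <- sum(tm * f) * dt / z
  m2 <- sum(tm^2 * f) * dt / z
  Fc <- 1 - solution$survival
  qs <- vapply(probs, function(p) {
    i <- which(Fc >= p * ab)[1]
    solution$t[i]
  }, numeric(1))
  list(mean = m1, var = m2 - m1^2, sd = sqrt(max(0, m2 - m1^2)),
       quantiles = setNames(qs, paste0("q", probs)), absorbed_total = ab)
}

#' Inverse-Gaussian first-passage CDF
#'
#' Closed-form distribution of the first-passage time of a constant
#' drift-diffusion process to a single absorbing threshold: mean
#' `mu = eta tau / alpha`, shape `lambda = eta^2 tau^2 / sigma^2`.
#' Used as the analytic oracle for the constant-drift Fokker-Planck
#' solution.
#'
#' @param t times (> 0).
#' @param mu mean of the distribution.
#' @param lambda shape parameter.
#' @return CDF values.
#' @export
pinvgauss <- function(t, mu, lambda) {
  stopifnot(mu > 0, lambda > 0)
  out <- numeric(length(t))
  pos <- t > 0
  tt <- t[pos]
  a <- sqrt(lambda / tt)
  out[pos] <- pnorm(a * (tt / mu - 1)) +
    exp(2 * lambda / mu + pnorm(-a * (tt / mu + 1), log.p = TRUE))
  out
}

#' Sample patch-leaving times from the stochastic simulator
#'
#' Euler-Maruyama first-passage sampler for a single patch with the
#' energy estimate (and hence the threshold) held fixed: the Monte-Carlo
#' counterpart of [solve_density()], and the natural tool for validating
#' the Fokker-Planck solution against the trajectory-level model.
#'
#' @param n number of independent patch visits.
#' @param alpha drift rate.
#' @param eta threshold (fixed for the whole visit).
#' @param sigma,tau noise amplitude and decision timescale.
#' @param rho0,A patch parameters (`rho0 = 0` gives a constant-drift
#'   process).
#' @param c chunk size; 0 = continuous reward.
#' @param dt integration step.
#' @param t_max give up after this long (unabsorbed visits return `NA`).
#' @param exact_decay with continuous rewards, feed the exact mean
#'   stream `rho0 exp(-t/A)` instead of Euler-depleting the density
#'   (this is the SDE the Fokker-Planck problem describes).
#' @return A data frame with `t` (leaving time, `NA` if never crossed),
#'   `food` (total energy eaten) and `chunks`.
#' @export
sample_leave_times <- function(n, alpha, eta, sigma, tau = 1, rho0 = 0, A = 1,
                               c = 0, dt = 0.01, t_max = 1000,
                               exact_decay = FALSE) {
  stopifnot(n >= 1, eta != 0, sigma >= 0, tau > 0, rho0 >= 0, A > 0, c >= 0,
            dt > 0, t_max > dt)
  out <- fpt_sample_cpp(as.integer(n), alpha, eta, sigma, tau, rho0, A, c,
                        dt, t_max, exact_decay)
  data.frame(t = out$t, food = out$food, chunks = out$chunks)
}
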