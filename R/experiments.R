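#' Simulate a full foraging session
#'
#' Alternates patch and travel phases from `t = 0` (the forager enters
#' its first patch immediately, with energy estimate `e_init`), using
#' the compiled Euler-Maruyama stepper.  Averages are taken over a
#' measurement window that starts at the first patch entry at or after
#' `burn_in` and covers only *complete* cycles (a patch plus the travel
#' that follows it) finishing by `total_time`, so initialization
#' transients and partial cycles never bias the summary statistics.
#'
#' @param env an [environment_spec()].
#' @param strategy a [strategy_params()]; its `rho0_bar`/`A_bar` are the
#'   means the forager assumes (normally the environment means).
#' @param utility a [utility_config()].
#' @param cfg an [sde_config()].
#' @param total_time session length (default `20000` time units).
#' @param burn_in discarded initial period (default `1000`).
#' @param e_init initial energy estimate.
#' @param freeze_e if `TRUE`, hold the energy estimate fixed at `e_init`
#'   (the analytically solvable regime).
#' @param update_each_step if `TRUE` (default) the threshold - and the
#'   size-adaptive drift - are recomputed every integration step from
#'   the running energy estimate; if `FALSE` they are frozen at each
#'   patch entry.
#' @param seed RNG seed; defaults to `cfg$seed`.  `NULL` uses the
#'   current RNG state.
#' @return An object of class `fddm_session`: a list with `visits` (one
#'   row per completed cycle, including `in_window`), `summary` (window
#'   statistics), and the configuration used.  Summary fields:
#'   `mean_energy_rate` (realized net intake over the window),
#'   `sd_energy_rate` (SD of per-cycle net rates), `mean_prt`/`sd_prt`,
#'   `chunk_histogram`, `n_patches`, `window`, and `mean_E_exit` (the
#'   forager's own estimate at patch exits, which converges to the
#'   realized rate in steady state).
#' @examples
#' env <- environment_spec(rho0 = 9.439, A = 5, t_travel = 5)
#' st <- strategy_params("density_adaptive", 9.439, 5, E = 2, s = 1)
#' s <- simulate_session(env, st, cfg = sde_config(sigma = 1), total_time = 2000,
#'                       burn_in = 200, seed = 1)
#' s$summary$mean_energy_rate
#' @export
simulate_session <- function(env, strategy, utility = utility_config(),
                             cfg = sde_config(), total_time = 20000,
                             burn_in = 1000, e_init = 0, freeze_e = FALSE,
                             update_each_step = TRUE, seed = cfg$seed) {
  stopifnot(inherits(env, "environment_spec"),
            inherits(strategy, "strategy_params"),
            inherits(utility, "utility_config"),
            inherits(cfg, "sde_config"),
            total_time > burn_in, burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  u_form <- match(utility$form, c("none", "exponential", "threshold_linear")) - 1L
  max_patches <- as.integer(min(5e6, ceiling(total_time / cfg$dt) + 1000))
  raw <- sim_session_cpp(
    env$rho0, env$rho0_sd, env$A, env$A_sd, env$c,
    env$t_travel, env$travel == "exponential", env$s,
    strategy$rho0_bar, strategy$A_bar,
    strategy$kind == "size_adaptive", strategy$alpha,
    cfg$tau, cfg$tau_E, cfg$sigma, cfg$dt,
    u_form, utility$beta, utility$floor,
    total_time, e_init, freeze_e, update_each_step, max_patches)
  visits <- data.frame(t_enter = raw$t_enter, t_leave = raw$t_leave,
                       prt = raw$t_leave - raw$t_enter,
                       chunks = raw$chunks, food = raw$food,
                       E_exit = raw$E_exit, travel_after = raw$travel_after,
                       rho0_actual = raw$rho0_actual, A_actual = raw$A_actual,
                       degenerate = raw$degenerate)
  visits$in_window <- visits$t_enter >= burn_in
  w <- visits[visits$in_window, , drop = FALSE]
  if (nrow(w) == 0)
    stop("no complete patch+travel cycle inside the measurement window; ",
         "increase total_time or decrease burn_in")
  cyc <- w$prt + w$travel_after
  len <- sum(cyc)
  summary <- list(
    mean_energy_rate = (sum(w$food) - env$s * len) / len,
    sd_energy_rate = sd((w$food - env$s * cyc) / cyc),
    mean_prt = mean(w$prt), sd_prt = sd(w$prt),
    chunk_histogram = table(w$chunks),
    n_patches = nrow(w),
    window = c(t_start = w$t_enter[1],
               t_end = w$t_leave[nrow(w)] + w$travel_after[nrow(w)]),
    mean_E_exit = mean(w$E_exit),
    n_degenerate = raw$n_degenerate)
  structure(list(visits = visits, summary = summary, env = env,
                 strategy = strategy, utility = utility, cfg = cfg,
                 total_time = total_time, burn_in = burn_in,
                 e_init = e_init, freeze_e = freeze_e,
                 update_each_step = update_each_step, seed = seed),
            class = "fddm_session")
}

#' @export
print.fddm_session <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Foraging session (%s strategy, %d patches in window):\n", x$strategy$kind,
    s$n_patches),
    sprintf("  energy rate %.4f (sd %.4f)   PRT %.4f (sd %.4f)\n",
            s$mean_energy_rate, s$sd_energy_rate, s$mean_prt, s$sd_prt),
    sep = "")
  invisible(x)
}

#' Run a grid of foraging sessions
#'
#' Each cell of the grid is a full session configuration; every cell is
#' run for `replicates` seeds derived from `base_seed` by the rule
#' `seed = base_seed + (cell - 1) * replicates + (replicate - 1)`, so
#' any cell/replicate can be reproduced in isolation.  Per-cell failures
#' are recorded in the `error` column instead of aborting the sweep.
#'
#' @param cells a named list; each element is a list with components
#'   `env`, `strategy`, and optionally `utility`, `cfg`, `e_init`,
#'   `freeze_e`, `update_each_step`.
#' @param replicates seeds per cell.
#' @param base_seed base of the seed-splitting rule.
#' @param total_time,burn_in session length and burn-in for every cell.
#' @return A data frame with one row per cell and replicate: the cell
#'   name, seed, summary statistics, and an `error` column (`NA` on
#'   success).
#' @export
sweep_sessions <- function(cells, replicates = 3, base_seed = 1,
                           total_time = 20000, burn_in = 1000) {
  stopifnot(length(cells) > 0)
  if (is.null(names(cells))) names(cells) <- sprintf("cell%02d", seq_along(cells))
  rows <- list()
  for (j in seq_along(cells)) {
    cell <- cells[[j]]
    for (r in seq_len(replicates)) {
      seed <- base_seed + (j - 1L) * replicates + (r - 1L)
      res <- tryCatch({
        ses <- simulate_session(
          env = cell$env, strategy = cell$strategy,
          utility = if (is.null(cell$utility)) utility_config() else cell$utility,
          cfg = if (is.null(cell$cfg)) sde_config() else cell$cfg,
          total_time = total_time, burn_in = burn_in,
          e_init = if (is.null(cell$e_init)) 0 else cell$e_init,
          freeze_e = isTRUE(cell$freeze_e),
          update_each_step = if (is.null(cell$update_each_step)) TRUE
                             else cell$update_each_step,
          seed = seed)
        s <- ses$summary
        data.frame(cell = names(cells)[j], replicate = r, seed = seed,
                   mean_energy_rate = s$mean_energy_rate,
                   sd_energy_rate = s$sd_energy_rate,
                   mean_prt = s$mean_prt, sd_prt = s$sd_prt,
                   n_patches = s$n_patches, error = NA_character_,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(cell = names(cells)[j], replicate = r, seed = seed,
                   mean_energy_rate = NA_real_, sd_energy_rate = NA_real_,
                   mean_prt = NA_real_, sd_prt = NA_real_,
                   n_patches = NA_integer_, error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Reference grid of foraging environments
#'
#' The 3 x 3 x 2 grid of available energy (`E* = 0.5, 2, 5`), travel
#' time (`T_tr = 1, 5, 10`) and patch size (`A = 1.5, 5`), each with the
#' initial density solved from the MVT self-consistency conditions
#' ([solve_environment()]) so the environment really affords the stated
#' `E*`.  The alias `"medium-default"` names the intermediate
#' configuration (`E* = 2`, `T_tr = 5`, `A = 5`, `rho0 = 9.439`).
#'
#' @param s constant cost (default 1, the energy unit).
#' @return A named list; each element has `env` (an
#'   [environment_spec()]), `E_star`, `T_star` and `rho0`.
#' @export
environment_presets <- function(s = 1) {
  out <- list()
  for (E in c(0.5, 2, 5)) for (Ttr in c(1, 5, 10)) for (A in c(1.5, 5)) {
    sol <- solve_environment(A = A, T_tr = Ttr, s = s, E_star = E)
    nm <- sprintf("E%g_Ttr%g_A%g", E, Ttr, A)
    out[[nm]] <- list(env = environment_spec(rho0 = sol$rho0, A = A,
                                             t_travel = Ttr, s = s),
                      E_star = E, T_star = sol$T_star, rho0 = sol$rho0)
  }
  out[["medium-default"]] <- out[["E2_Ttr5_A5"]]
  out
}

#' Slope of patch residence time against realized patch density
#'
#' Least-squares slope of the per-visit residence time against the
#' visited patch's drawn initial density, for comparison with the
#' first-order prediction of [prt_sensitivity_density()].  A positive
#' slope means the forager stays longer in richer patches (the
#' MVT-optimal direction); decremental strategies produce negative
#' slopes.
#'
#' @param visits the `visits` data frame of an [simulate_session()]
#'   result (window visits are used if the `in_window` column is
#'   present).
#' @param min_visits minimum number of visits required.
#' @return A list with `slope`, `stderr` and `n`.
#' @export
prt_regression <- function(visits, min_visits = 30) {
  if (!is.null(visits$in_window)) visits <- visits[visits$in_window, , drop = FALSE]
  if (nrow(visits) < min_visits)
    stop(sprintf("need at least %d visits, got %d", min_visits, nrow(visits)))
  if (sd(visits$rho0_actual) < 1e-12)
    stop("patch density is constant across visits; the slope is undefined")
  fit <- lm(prt ~ rho0_actual, data = visits)
  co <- summary(fit)$coefficients
  list(slope = unname(co["rho0_actual", "Estimate"]),
       stderr = unname(co["rho0_actual", "Std. Error"]),
       n = nrow(visits))
}

#' Stable hash of a configuration object
#'
#' 32-bit FNV-1a over the deparsed object; used to stamp output files so
#' any artifact records which configuration produced it.
#'
#' @param x any R object.
#' @return An 8-character hex string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "\n")
  bytes <- utf8ToInt(txt)
  # FNV-1a in double arithmetic; XOR on 16-bit halves keeps every operand
  # inside the integer range bitwXor accepts
  xor32 <- function(a, b) {
    bitwXor(a %% 65536, b %% 65536) +
      65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply in 16-bit limbs (exact in double arithmetic)
    h <- (h %% 65536 * p + (h %/% 65536 * p) %% 65536 * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

.visit_columns <- c("t_enter", "t_leave", "prt", "chunks", "food", "E_exit",
                    "travel_after", "rho0_actual", "A_actual", "degenerate",
                    "in_window")

#' Write and read a visit table
#'
#' Visits are written as CSV with a fixed column order, preceded by
#' comment lines embedding the configuration hash and seed; the reader
#' skips them, so a round trip reproduces the table exactly.
#'
#' @param visits visit data frame (from [simulate_session()]).
#' @param path output file.
#' @param hash,seed provenance stamps (defaults: hash of the table, no
#'   seed).
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, hash = config_hash(visits), seed = NA) {
  cols <- intersect(.visit_columns, names(visits))
  visits <- visits[, cols, drop = FALSE]
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  writeLines(sprintf("# seed: %s", seed), con)
  write.csv(visits, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visits
#' @export
read_visits <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a session summary as JSON
#'
#' @param summary the `summary` element of an [simulate_session()]
#'   result.
#' @param path output file.
#' @param hash,seed provenance stamps.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, hash = config_hash(summary), seed = NA) {
  out <- summary
  out$chunk_histogram <- as.list(setNames(as.integer(summary$chunk_histogram),
                                          names(summary$chunk_histogram)))
  out$config_hash <- hash
  out$seed <- seed
  tryCatch(jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}
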