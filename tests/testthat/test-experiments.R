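test_that("sessions are deterministic given a seed", {
  env <- ref_env(rho0_sd = 0.3 * ref_rho0, c = 8, travel = "exponential")
  st <- ref_strategy("density_adaptive")
  cfg <- sde_config(sigma = 2)
  a <- simulate_session(env, st, cfg = cfg, total_time = 2000, burn_in = 200,
                        seed = 9)
  b <- simulate_session(env, st, cfg = cfg, total_time = 2000, burn_in = 200,
                        seed = 9)
  expect_identical(a$visits, b$visits)
  expect_identical(a$summary$mean_energy_rate, b$summary$mean_energy_rate)
})

test_that("the measurement window covers whole cycles exactly", {
  env <- ref_env(rho0_sd = 0.2 * ref_rho0, travel = "exponential")
  st <- ref_strategy("density_adaptive")
  ses <- simulate_session(env, st, cfg = sde_config(sigma = 2),
                          total_time = 3000, burn_in = 500, seed = 10)
  w <- ses$visits[ses$visits$in_window, ]
  expect_true(all(w$t_enter >= 500))
  # cycles abut: sum of (prt + travel) equals the window span
  expect_equal(sum(w$prt + w$travel_after),
               unname(ses$summary$window["t_end"] - ses$summary$window["t_start"]),
               tolerance = 1e-9)
  # last cycle completes before the session end
  expect_lte(unname(ses$summary$window["t_end"]), 3000 + 1e-9)
  # the reported net rate is the trajectory-level time average over the window
  len <- sum(w$prt + w$travel_after)
  expect_equal(ses$summary$mean_energy_rate,
               (sum(w$food) - env$s * len) / len, tolerance = 1e-12)
  # per-visit conservation
  expect_true(all(w$food <= w$rho0_actual * w$A_actual + 1e-9))
})

test_that("frozen-estimate noiseless sessions reproduce the MVT optimum", {
  env <- ref_env()
  for (k in c("density_adaptive", "robust_counting", "counting")) {
    ses <- simulate_session(env, ref_strategy(k), total_time = 3000,
                            burn_in = 500, e_init = 2, freeze_e = TRUE,
                            seed = 1)
    expect_lt(max(abs(ses$visits$prt - ref_Tstar)), sde_config()$dt + 1e-9)
    expect_equal(ses$summary$mean_energy_rate, 2, tolerance = 0.01)
  }
})

test_that("satisficing utilities lengthen patch residence for both strategies", {
  env <- ref_env(rho0_sd = 0.3 * ref_rho0)
  cfg <- sde_config(sigma = 0.3 * ref_rho0)
  for (k in c("density_adaptive", "robust_counting")) {
    st <- ref_strategy(k)
    base <- simulate_session(env, st, cfg = cfg, total_time = 4000, seed = 31)
    for (u in list(utility_config("exponential", beta = 0.5),
                   utility_config("threshold_linear", beta = 0.2, floor = 0.65))) {
      ses <- simulate_session(env, st, utility = u, cfg = cfg,
                              total_time = 4000, seed = 31)
      expect_gte(ses$summary$mean_prt, base$summary$mean_prt)
    }
  }
})

test_that("sweeps run every cell and record per-cell failures", {
  env <- ref_env()
  st <- ref_strategy("density_adaptive")
  cells <- list(
    quiet = list(env = env, strategy = st, cfg = sde_config(sigma = 0.5)),
    noisy = list(env = env, strategy = st, cfg = sde_config(sigma = 2)),
    # travel longer than the whole window: no complete cycle fits
    broken = list(env = ref_env(t_travel = 5000), strategy = st))
  res <- sweep_sessions(cells, replicates = 2, base_seed = 1,
                        total_time = 1500, burn_in = 300)
  expect_equal(nrow(res), 6)
  expect_equal(res$seed, c(1, 2, 3, 4, 5, 6))
  ok <- res$cell != "broken"
  expect_true(all(is.na(res$error[ok])))
  expect_true(all(!is.na(res$error[!ok])))
  expect_true(all(is.na(res$mean_prt[!ok])))
  # noisier cells have more variable residence times
  expect_gt(mean(res$sd_prt[res$cell == "noisy"]),
            mean(res$sd_prt[res$cell == "quiet"]))
})

test_that("the preset grid affords the stated energy rates", {
  pr <- environment_presets()
  expect_length(pr, 19)  # 3 x 3 x 2 grid plus the medium-default alias
  md <- pr[["medium-default"]]
  expect_equal(round(md$rho0, 3), 9.439)
  expect_equal(md$E_star, 2)
  expect_equal(pr[["E0.5_Ttr1_A1.5"]]$rho0, 3.9538, tolerance = 1e-4)
  for (p in pr) {
    expect_gt(p$rho0, p$E_star + p$env$s)
    # the solved density really yields E* back
    expect_equal(solve_environment(A = p$env$A, T_tr = p$env$t_travel,
                                   s = p$env$s, rho0 = p$rho0)$E_star,
                 p$E_star, tolerance = 1e-6)
  }
})

test_that("residence-vs-density slopes recover the first-order prediction", {
  env <- ref_env(rho0_sd = 0.02 * ref_rho0)
  st <- ref_strategy("density_adaptive")
  ses <- simulate_session(env, st, total_time = 5000, burn_in = 500,
                          e_init = 2, freeze_e = TRUE, seed = 5)
  fit <- prt_regression(ses$visits)
  expect_equal(fit$slope, 5 / ref_rho0, tolerance = 0.05)
  # degenerate variance is rejected
  fixed <- simulate_session(ref_env(), st, total_time = 2000, burn_in = 200,
                            e_init = 2, freeze_e = TRUE, seed = 6)
  expect_error(prt_regression(fixed$visits), "constant")
})

test_that("visit tables and summaries round-trip through disk", {
  env <- ref_env(rho0_sd = 0.2 * ref_rho0, c = 8)
  st <- ref_strategy("density_adaptive")
  ses <- simulate_session(env, st, cfg = sde_config(sigma = 1),
                          total_time = 1200, burn_in = 200, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_visits(ses$visits, f, seed = 12)
  back <- read_visits(f)
  expect_equal(back$prt, ses$visits$prt)
  expect_equal(back$food, ses$visits$food)
  expect_equal(names(back),
               c("t_enter", "t_leave", "prt", "chunks", "food", "E_exit",
                 "travel_after", "rho0_actual", "A_actual", "degenerate",
                 "in_window"))
  expect_match(readLines(f, n = 2)[1], "config_hash")

  # empty table -> header-only CSV
  f2 <- tempfile(fileext = ".csv")
  write_visits(ses$visits[0, ], f2)
  expect_equal(nrow(read_visits(f2)), 0)

  f3 <- tempfile(fileext = ".json")
  write_summary(ses$summary, f3, seed = 12)
  js <- jsonlite::read_json(f3)
  expect_true(all(c("mean_energy_rate", "sd_energy_rate", "mean_prt", "sd_prt",
                    "chunk_histogram", "n_patches", "window", "config_hash",
                    "seed") %in% names(js)))
  expect_equal(js$mean_energy_rate, ses$summary$mean_energy_rate)
})
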