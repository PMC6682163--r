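test_that("optimal residence time follows the marginal-value closed form", {
  expect_equal(optimal_patch_time(9.439, 5, 2, 1), 5 * log(9.439 / 3))
  expect_equal(optimal_patch_time(3, 5, 2, 1), 0)      # rho0 = E + s
  expect_equal(optimal_patch_time(9.439, 10, 2, 1),
               2 * optimal_patch_time(9.439, 5, 2, 1)) # linear in A
  expect_error(optimal_patch_time(2.9, 5, 2, 1), "exceed")
})

test_that("the medium environment solves to rho0 = 9.439 and back", {
  sol <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)
  expect_equal(round(sol$rho0, 3), 9.439)
  expect_equal(sol$T_star, 5 * log(sol$rho0 / 3))

  back <- solve_environment(A = 5, T_tr = 5, s = 1, rho0 = sol$rho0)
  expect_equal(back$E_star, 2, tolerance = 1e-8)

  low <- solve_environment(A = 1.5, T_tr = 1, s = 1, E_star = 0.5)
  expect_equal(low$rho0, 3.9538, tolerance = 1e-4)

  # vanishing travel time: marginal and average rates coincide at zero
  # residence (rho0 - (E+s) shrinks like sqrt(T_tr))
  tiny <- solve_environment(A = 5, T_tr = 1e-9, s = 1, E_star = 2)
  expect_lt(tiny$rho0 - 3, 1.1 * sqrt(6 * 3 * 1e-9 / 5))
  expect_lt(tiny$T_star, 1e-4)
})

test_that("E* -> rho0 -> E* round-trips across random environments", {
  set.seed(201)
  for (i in 1:10) {
    A <- runif(1, 1, 8); Ttr <- runif(1, 0.5, 12); s <- runif(1, 0.5, 2)
    Es <- runif(1, 0.2, 5)
    r <- solve_environment(A = A, T_tr = Ttr, s = s, E_star = Es)$rho0
    expect_equal(solve_environment(A = A, T_tr = Ttr, s = s, rho0 = r)$E_star,
                 Es, tolerance = 1e-8)
  }
})

test_that("optimal thresholds take the closed-form values per strategy", {
  expect_equal(optimal_threshold(9.439, 9.439, 5, 2, 1), 21.9016907847,
               tolerance = 1e-9)
  expect_equal(optimal_threshold(0, 9.439, 5, 2, 1), -32.195)
  aS <- (9.439 - 3) / log(9.439 / 3)
  expect_equal(optimal_threshold(aS, 9.439, 5, 2, 1), 0, tolerance = 1e-10)
  expect_error(optimal_threshold(1, 2.9, 5, 2, 1), "undefined")
})

test_that("named strategies set the documented drift rates", {
  da <- strategy_params("density_adaptive", 9.439, 5, E = 2, s = 1)
  expect_equal(da$alpha, 9.439)
  expect_equal(strategy_params("counting", 9.439, 5, E = 2, s = 1)$alpha, 0)
  sa <- strategy_params("size_adaptive", 9.439, 5, E = 2, s = 1)
  expect_equal(sa$alpha, 5.6175082, tolerance = 1e-7)
  expect_equal(sa$eta, 0, tolerance = 1e-10)
  rc <- strategy_params("robust_counting", 9.439, 5, E = 2, s = 1)
  expect_equal(rc$alpha, -0.2 * 9.439)
  expect_lt(rc$eta, 0)
  expect_error(strategy_params("robust_counting", 9.439, 5, 2, 1,
                               rc_scale = 0.1), "rc_scale")
})

test_that("drift validity excludes the double-crossing and opposite-sign bands", {
  v <- drift_validity(4, 9.439, 5, 2, 1)
  expect_equal(v$alpha_crit, 3)
  expect_equal(v$alpha_S, 5.6175082, tolerance = 1e-7)
  expect_false(v$valid)                                  # inside the band
  expect_true(drift_validity(-1, 9.439, 5, 2, 1)$valid)  # decremental
  expect_true(drift_validity(9.439, 9.439, 5, 2, 1)$valid)
  expect_true(drift_validity(v$alpha_S, 9.439, 5, 2, 1)$valid)
})

test_that("expected chunk count scales inversely with chunk size", {
  rho0 <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)$rho0
  expect_equal(round(n_opt(rho0, 5, 8, 2, 1), 2), 4.02)
  expect_equal(n_opt(rho0, 5, 5 * (rho0 - 3), 2, 1), 1)
  expect_equal(n_opt(rho0, 5, 4, 2, 1), 2 * n_opt(rho0, 5, 8, 2, 1))
  expect_error(n_opt(rho0, 5, 0, 2, 1), "chunk size")
})

test_that("sensitivity predictions reduce to the optimal adjustments", {
  # frozen reference values in the medium environment
  expect_equal(prt_sensitivity_density(9.439, 9.439, 5, 2, 1)$dT_drho0,
               5 / 9.439)
  expect_equal(prt_sensitivity_density(0, 9.439, 5, 2, 1)$dT_drho0,
               -1.13694954, tolerance = 1e-7)
  expect_equal(prt_sensitivity_size(9.439, 9.439, 2, 1)$dT_dA,
               0.46595539, tolerance = 1e-7)
  aS <- (9.439 - 3) / log(9.439 / 3)
  expect_equal(prt_sensitivity_size(aS, 9.439, 2, 1)$dT_dA, log(9.439 / 3))

  # reductions hold for randomized parameter sets
  set.seed(202)
  for (i in 1:10) {
    E <- runif(1, 0.2, 4); s <- runif(1, 0.5, 2)
    r <- (E + s) * exp(runif(1, 0.3, 2)); A <- runif(1, 1, 8)
    expect_equal(prt_sensitivity_density(r, r, A, E, s)$dT_drho0, A / r)
    aS <- (r - E - s) / log(r / (E + s))
    expect_equal(prt_sensitivity_size(aS, r, E, s)$dT_dA, log(r / (E + s)))
    # decremental strategies leave richer patches sooner
    expect_lt(prt_sensitivity_density(-runif(1, 0.05, 1) * r, r, A, E, s)$dT_drho0, 0)
  }
  expect_error(prt_sensitivity_density(3, 9.439, 5, 2, 1), "singular")
})

test_that("the counting identity ties food target, chunk count and threshold", {
  rho0 <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)$rho0
  a <- 5 * (rho0 - 3)
  b <- n_opt(rho0, 5, 8, 2, 1) * 8
  d <- abs(optimal_threshold(0, rho0, 5, 2, 1))
  expect_lt(abs(a - b), 1e-10)
  expect_lt(abs(a - d), 1e-10)
})

test_that("noiseless crossing times match a fine-grid integration oracle", {
  # frozen values from independent Euler integration at dt = 1e-6
  expect_equal(deterministic_prt(-1, -12, 6, 3), 2.31642, tolerance = 1e-4)
  expect_equal(deterministic_prt(7, 4, 6, 3), 1.66829, tolerance = 1e-4)
  # MVT equivalence of all four strategies at the consistent (alpha, eta)
  rho0 <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)$rho0
  Ts <- optimal_patch_time(rho0, 5, 2, 1)
  for (k in c("density_adaptive", "size_adaptive", "counting",
              "robust_counting")) {
    st <- strategy_params(k, rho0, 5, E = 2, s = 1)
    expect_equal(deterministic_prt(st$alpha, st$eta, rho0, 5), Ts,
                 tolerance = 1e-8)
  }
  # a pure counter in a patch that cannot deliver |eta| of food never leaves
  expect_identical(deterministic_prt(0, -(6 * 3 + 1), 6, 3), Inf)
})

test_that("the satisficing fixed point recovers MVT at beta = 0 and lengthens stays", {
  rho0 <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)$rho0
  u0 <- utility_fixed_point("density_adaptive", utility_config("none"),
                            5, 5, 1, rho0)
  expect_equal(u0$E, u0$E_star, tolerance = 1e-7)
  expect_equal(u0$T, u0$T_star, tolerance = 1e-6)

  for (u in list(utility_config("exponential", beta = 0.5),
                 utility_config("threshold_linear", beta = 0.2, floor = 0.65))) {
    for (k in c("density_adaptive", "robust_counting")) {
      fx <- utility_fixed_point(k, u, 5, 5, 1, rho0)
      expect_gte(fx$T, fx$T_star)
      expect_lte(fx$E, fx$E_star)
    }
  }

  # in a barely-viable environment the solution approaches the MVT optimum
  poor <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 0.01)$rho0
  ue <- utility_config("exponential", beta = 0.5)
  fx_poor <- utility_fixed_point("density_adaptive", ue, 5, 5, 1, poor)
  fx_med <- utility_fixed_point("density_adaptive", ue, 5, 5, 1, rho0)
  expect_lt(fx_poor$T - fx_poor$T_star, 0.1 * (fx_med$T - fx_med$T_star))
})
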