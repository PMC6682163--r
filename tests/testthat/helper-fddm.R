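# Shared fixtures: the intermediate reference environment (A = 5, T_tr = 5,
# s = 1, E* = 2, rho0 = 9.439) and an R-level reference session driver used
# to check the compiled simulator step by step.

ref_rho0 <- solve_environment(A = 5, T_tr = 5, s = 1, E_star = 2)$rho0  # 9.4386
ref_Tstar <- optimal_patch_time(ref_rho0, A = 5, E = 2, s = 1)           # 5.7310

ref_env <- function(...) {
  args <- modifyList(list(rho0 = ref_rho0, A = 5, t_travel = 5, s = 1),
                     list(...))
  do.call(environment_spec, args)
}

ref_strategy <- function(kind, E = 2, rho0_bar = ref_rho0, A_bar = 5, s = 1,
                         rc_scale = -0.2) {
  strategy_params(kind, rho0_bar = rho0_bar, A_bar = A_bar, E = E, s = s,
                  rc_scale = rc_scale)
}

# Drive the published single-step R operations through n_patches complete
# patch+travel cycles, consuming the RNG in exactly the order the compiled
# session loop does.  Used by the parity test.
r_reference_session <- function(env, strategy, utility, cfg, n_patches,
                                e_init = 0) {
  E <- e_init
  t <- 0
  visits <- list()
  for (p in seq_len(n_patches)) {
    patch <- draw_patch(env)
    state <- forager_state(x = 0, E = E, phase = "in_patch", t = t,
                           patch = patch)
    food_tot <- 0
    repeat {
      state <- step_in_patch(state, strategy, utility, cfg, env)
      food_tot <- food_tot + state$food
      if (state$crossed) break
    }
    E_exit <- state$E
    prt <- state$t_phase
    ttr <- draw_travel_time(env)
    trav <- forager_state(x = 0, E = state$E, phase = "traveling",
                          t = state$t)
    while (ttr - trav$t_phase > 1e-12) {
      h <- min(cfg$dt, ttr - trav$t_phase)
      trav <- step_travel(trav, cfg, env, dt = h)
    }
    E <- trav$E
    t <- trav$t
    visits[[p]] <- data.frame(prt = prt, food = food_tot, E_exit = E_exit,
                              travel_after = ttr,
                              rho0_actual = patch$spec$rho0,
                              A_actual = patch$spec$A)
  }
  do.call(rbind, visits)
}
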