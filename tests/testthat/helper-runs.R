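# Shared cache of reduced-scale (G = 8) study runs used by the acceptance
# tests: several criteria draw on the same conditions, so each condition is
# simulated once per session. Only the slim summary each test consumes is
# retained (full trajectories for ~60 runs would keep hundreds of MB live
# and throttle the garbage collector).
.run_cache <- new.env(parent = emptyenv())

study_summary <- function(T_r = 1, ratio = 1, interval = 400, seed = 1,
                          S_c = 0.05, n_breaths = 800) {
  key <- paste(T_r, ratio, interval, seed, S_c, n_breaths, sep = "|")
  if (is.null(.run_cache[[key]])) {
    cfg <- sim_config(generations = 8, T_r = T_r, S_c = S_c, seed = seed,
                      schedule = di_schedule(interval, ratio),
                      n_breaths = n_breaths)
    traj <- run_simulation(cfg)
    rs <- resistance_series(traj)
    .run_cache[[key]] <- list(
      fc_mean = fc_mean(traj),
      vent_final = traj$ventilation[nrow(traj$ventilation), ],
      r6hz = traj$r6hz, R0 = rs$R0, di_breaths = traj$di_breaths)
  }
  .run_cache[[key]]
}

study_fc <- function(...) study_summary(...)$fc_mean
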