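#' Breath-to-breath radius update
#'
#' The discrete relaxation of an airway radius toward its predicted steady
#' state: \eqn{r(k+1) = r(k) + S_x (r^*(k) - r(k))}, with the constriction
#' speed index \eqn{S_x = S_c} when \eqn{r^* < r} and the dilation speed
#' index \eqn{S_x = S_d} when \eqn{r^* > r}. The defaults
#' \eqn{S_c = 0.05, S_d = 0.33} correspond to 12 breaths/min: constriction
#' is an order of magnitude slower per breath than dilation.
#'
#' @param r Current radius (cm), vectorized.
#' @param r_star Predicted steady-state radius (cm).
#' @param S_c Constriction speed index in (0, 1].
#' @param S_d Dilation speed index in (0, 1].
#' @return Updated radius (cm).
#' @export
update_radius <- function(r, r_star, S_c = 0.05, S_d = 0.33) {
  stopifnot(all(r > 0), all(r_star > 0),
            S_c > 0, S_c <= 1, S_d > 0, S_d <= 1)
  S_x <- ifelse(r_star < r, S_c, S_d)
  r + S_x * (r_star - r)
}

#' Tidal volume matching a target mean ventilation
#'
#' For a DI cycle of \code{n} breaths containing one DI of volume
#' \code{ratio} times the tidal volume, returns the tidal volume that makes
#' the cycle's mean breath volume equal the target:
#' \eqn{V_T = n \bar V / (n - 1 + ratio)}.
#'
#' @param mean_volume Target mean volume per breath (mL).
#' @param ratio Relative DI volume \eqn{V_{DI}/V_T} (>= 1).
#' @param n Breaths per DI cycle (>= 1).
#' @return Tidal volume (mL) of the breaths between DIs.
#' @export
tidal_volume_for_mean <- function(mean_volume, ratio, n) {
  stopifnot(n >= 1, ratio >= 1, mean_volume > 0)
  n * mean_volume / (n - 1 + ratio)
}

#' Periodic deep-inspiration schedule
#'
#' A DI cycle of \code{interval / duration} breaths: one DI followed by
#' \code{n - 1} tidal breaths, volumes adjusted so every condition delivers
#' the same mean ventilation. \code{ratio = 1} degenerates to uniform tidal
#' breathing without DIs.
#'
#' @param interval DI cycle interval (s); must be a multiple of the breath
#'   duration.
#' @param ratio Relative DI volume \eqn{V_{DI}/V_T} (>= 1).
#' @param duration Breath duration (s).
#' @param mean_volume Target mean volume per breath (mL).
#' @return A list of class \code{di_schedule} with the per-breath volume
#'   sequence of one cycle (\code{$volumes}, DI first), \code{$n},
#'   \code{$interval}, \code{$ratio}, \code{$duration},
#'   \code{$mean_volume}, \code{$tidal_volume}, \code{$di_volume}.
#' @export
di_schedule <- function(interval, ratio = 1, duration = 5,
                        mean_volume = 500) {
  stopifnot(interval > 0, duration > 0, ratio >= 1)
  n <- interval / duration
  if (abs(n - round(n)) > 1e-9) {
    stop("DI cycle interval must be a multiple of the breath duration")
  }
  n <- as.integer(round(n))
  V_T <- tidal_volume_for_mean(mean_volume, ratio, n)
  volumes <- c(ratio * V_T, rep(V_T, n - 1L))
  structure(list(interval = interval, ratio = ratio, duration = duration,
                 mean_volume = mean_volume, n = n, tidal_volume = V_T,
                 di_volume = ratio * V_T, volumes = volumes),
            class = "di_schedule")
}

#' Simulation configuration
#'
#' Bundles everything one run needs: tree scale, smooth-muscle activation
#' and speed indexes, wall-thickness perturbation, DI schedule, breath
#' specification and wall-model parameters.
#'
#' @param generations Tree generations G (12 for the full-scale tree, 8 for
#'   the reduced demo scale).
#' @param T_r Relative smooth-muscle activation in [0, 1].
#' @param S_c,S_d Constriction/dilation speed indexes (per breath).
#' @param cv Coefficient of variation of the wall-thickness perturbation.
#' @param seed Integer seed for the run's single RNG stream (perturbation is
#'   drawn first, the plotting subset of terminal airways second).
#' @param schedule A [di_schedule()].
#' @param n_breaths Number of breaths (default 800, i.e. 4000 s at 5 s
#'   breaths, enough to reach a stable state).
#' @param spec A [breath_spec()]; its tidal volume is overridden breath by
#'   breath from the schedule.
#' @param params A [wall_params()].
#' @param total_compliance Total respiratory compliance (mL/cmH2O).
#' @param morphometry Morphometry table (see [build_tree()]).
#' @param n_trace Number of randomly selected terminal airways whose radii
#'   are traced every breath (default 256); the full radius matrix is kept
#'   only for trees of 9 generations or fewer.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(generations = 8, T_r = 1, S_c = 0.05, S_d = 0.33,
                       cv = 0.01, seed = 1L,
                       schedule = di_schedule(400, 1, 5, 500),
                       n_breaths = 800L, spec = breath_spec(),
                       params = wall_params(), total_compliance = 100,
                       morphometry = default_morphometry(),
                       n_trace = 256L) {
  stopifnot(T_r >= 0, T_r <= 1, cv >= 0, n_breaths >= 1)
  if (n_breaths < schedule$n) {
    stop("run must cover at least one full DI cycle (", schedule$n,
         " breaths)")
  }
  structure(list(generations = as.integer(generations), T_r = T_r,
                 S_c = S_c, S_d = S_d, cv = cv, seed = as.integer(seed),
                 schedule = schedule, n_breaths = as.integer(n_breaths),
                 spec = spec, params = params,
                 total_compliance = total_compliance,
                 morphometry = morphometry, n_trace = as.integer(n_trace)),
            class = "sim_config")
}

#' Run a full bronchoconstriction simulation
#'
#' The main loop: each breath is simulated at fixed radii with the RC
#' network solver; every airway's predicted steady-state radius is then
#' computed from its peak transmural pressure during that breath, and the
#' radii relax toward it with the constriction/dilation speed indexes.
#' Radii start fully dilated with the smooth-muscle activation switched on
#' at breath 1. The run is fully deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param progress Print a progress line every 100 breaths.
#' @return An object of class \code{vdef_trajectory}: per-breath closed
#'   fractions (\code{$fc}), 6 Hz input resistance (\code{$r6hz},
#'   cmH2O s/L), per-breath tidal volumes, DI breath indices, ventilation
#'   matrix (breaths x terminal units, mL), radius traces
#'   (\code{$radii_trace}, breaths x traced airways, relative to r0,
#'   with \code{$trace_ids}; the full final radii in \code{$radii_final}),
#'   the perturbed \code{$tree}, and a config echo.
#' @export
run_simulation <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$generations
  base_tree <- build_tree(G, config$morphometry)
  n <- base_tree$n_airways
  nt <- base_tree$n_terminal
  term_ids <- which(!is.na(base_tree$airways$terminal_unit))

  # single RNG stream: perturbation first, plotting subset second
  state <- withr_seed(config$seed, {
    tree <- perturb_wall_thickness(base_tree, config$cv, seed = NULL)
    trace_ids <- if (config$n_trace < nt) {
      sort(sample(term_ids, config$n_trace))
    } else term_ids
    list(tree = tree, trace_ids = trace_ids)
  })
  tree <- state$tree
  trace_ids <- state$trace_ids

  r0 <- tree$airways$r0
  w <- tree$airways$w
  A <- config$params$P_a * config$T_r * w
  units <- terminal_units(tree, config$total_compliance)
  radii <- r0
  K <- config$n_breaths
  volumes <- config$schedule$volumes[((seq_len(K) - 1L) %%
                                        config$schedule$n) + 1L]
  di_breaths <- if (config$schedule$ratio > 1) {
    which(((seq_len(K) - 1L) %% config$schedule$n) == 0L)
  } else integer(0)

  keep_full <- G <= 9L
  vent <- matrix(NA_real_, K, nt)
  fc <- numeric(K)
  r6 <- numeric(K)
  radii_trace <- matrix(NA_real_, K, length(trace_ids))
  spec <- config$spec
  C_unit <- units$C_unit

  for (k in seq_len(K)) {
    spec$tidal_volume <- volumes[k]
    br <- simulate_breath(tree, radii, spec, units, config$params)
    units <- br$units
    vent[k, ] <- br$ventilation
    fc[k] <- closed_fraction(br$ventilation)
    r6[k] <- input_resistance(tree, radii, 6, C_unit)
    radii_trace[k, ] <- radii[trace_ids] / r0[trace_ids]
    sol <- solve_rstar_rel(br$ptm_peak, A, radii / r0, config$params)
    r_star <- sol$rho * r0
    radii <- update_radius(radii, r_star, config$S_c, config$S_d)
    if (progress && k %% 100L == 0L) {
      message(sprintf("breath %d/%d  Fc = %.3f", k, K, fc[k]))
    }
  }

  structure(list(config = config, tree = tree, fc = fc, r6hz = r6,
                 volumes = volumes, di_breaths = di_breaths,
                 ventilation = vent, radii_trace = radii_trace,
                 trace_ids = trace_ids, radii_final = radii,
                 r0 = r0, seed = config$seed),
            class = "vdef_trajectory")
}

#' @export
print.vdef_trajectory <- function(x, ...) {
  sched <- x$config$schedule
  cat("<vdef_trajectory> G =", x$config$generations,
      "| breaths =", length(x$fc),
      "| T_r =", x$config$T_r, "\n")
  cat("  DI: ratio", sched$ratio, "interval", sched$interval, "s |",
      "final Fc =", format(x$fc[length(x$fc)], digits = 3),
      "| Fc,mean =", format(fc_mean(x$fc, sched), digits = 3), "\n")
  invisible(x)
}
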