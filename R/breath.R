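#' Breath specification
#'
#' Timing, volume and physical constants for one simulated breath: a
#' constant-flow inspiration followed by passive exhalation to PEEP. The
#' defaults give 12 breaths/min (5 s breaths) with a 0.5 inspiratory
#' fraction, a 500 mL tidal volume and 10 ms solver steps.
#'
#' @param duration Breath duration (s).
#' @param insp_fraction Inspiratory fraction of the breath.
#' @param tidal_volume Inspired volume (mL).
#' @param peep Positive end-expiratory pressure (cmH2O); the pressure the
#'   airway opening is clamped to during passive expiration.
#' @param dt Solver time step (s); \code{duration/dt} must be an integer.
#' @param viscosity Air dynamic viscosity (Pa s).
#' @return A list of class \code{breath_spec}.
#' @export
breath_spec <- function(duration = 5, insp_fraction = 0.5,
                        tidal_volume = 500, peep = 5, dt = 0.010,
                        viscosity = 1.81e-5) {
  stopifnot(duration > 0, insp_fraction > 0, insp_fraction < 1,
            tidal_volume > 0, dt > 0, viscosity > 0)
  n_steps <- duration / dt
  if (abs(n_steps - round(n_steps)) > 1e-9) {
    stop("breath duration must be an integer number of time steps")
  }
  structure(list(duration = duration, insp_fraction = insp_fraction,
                 tidal_volume = tidal_volume, peep = peep, dt = dt,
                 viscosity = viscosity),
            class = "breath_spec")
}

#' Terminal-unit state
#'
#' Terminal (acinar) units are identical linear compliances. The total
#' respiratory compliance is split evenly over the \code{2^G} units; unit
#' volumes are tracked in mL above the relaxation volume at PEEP.
#'
#' @param tree An \code{airway_tree}.
#' @param total_compliance Total compliance (mL/cmH2O), default 100
#'   (0.1 L/cmH2O, adult-plausible).
#' @param volumes Initial unit volumes above relaxation (mL); scalar or
#'   one per unit.
#' @return A list of class \code{terminal_units} with \code{$C_unit} and
#'   \code{$V}.
#' @export
terminal_units <- function(tree, total_compliance = 100, volumes = 0) {
  stopifnot(inherits(tree, "airway_tree"), total_compliance > 0)
  V <- rep_len(volumes, tree$n_terminal)
  stopifnot(all(is.finite(V)))
  structure(list(C_unit = total_compliance / tree$n_terminal, V = V),
            class = "terminal_units")
}

#' Poiseuille resistance of an airway segment
#'
#' \eqn{R = 8 \mu L / (\pi r^4)}, converted to cmH2O s/mL from radius and
#' length in cm and viscosity in Pa s. Non-positive radii map to the
#' closed-airway sentinel \code{1e9} cmH2O s/mL (effectively infinite but
#' finite, so the network solve stays well-posed).
#'
#' @param radius Luminal radius (cm), vectorized.
#' @param length Segment length (cm).
#' @param viscosity Air dynamic viscosity (Pa s).
#' @return Resistance in cmH2O s/mL.
#' @export
airway_resistance <- function(radius, length, viscosity = 1.81e-5) {
  out <- rep(1e9, length(radius))
  ok <- radius > 0
  # 1 cmH2O = 98.0665 Pa; cm/mL units cancel to a single conversion factor
  out[ok] <- 8 * viscosity * length[ok] / (pi * radius[ok]^4) / 98.0665
  pmin(out, 1e9)
}

#' Simulate one breath at fixed airway radii
#'
#' Runs the within-breath RC solver: constant inspiratory flow
#' \code{tidal_volume / (insp_fraction * duration)} at the airway opening,
#' then passive expiration against PEEP, in backward-Euler steps of
#' \code{dt}. Airway resistances follow Poiseuille's law at the given
#' (breath-constant) radii. Records each airway's maximum transmural
#' pressure over the breath, where the transmural pressure combines the
#' mid-airway luminal pressure with elastic recoil amplified by parenchymal
#' tethering: regions inflating below the tree mean lose outward traction in
#' proportion to \code{tau} (see [wall_params()]).
#'
#' @param tree An \code{airway_tree}.
#' @param radii Per-airway luminal radii (cm), strictly positive.
#' @param spec A [breath_spec()].
#' @param units A [terminal_units()] state (start-of-breath volumes).
#' @param params A [wall_params()] (supplies \code{tau} and \code{P_el0}).
#' @param trace_airways Optional airway ids whose full transmural-pressure
#'   trace (one row per time step, cmH2O) is returned as
#'   \code{$ptm_trace}; its per-column maxima equal the corresponding
#'   \code{$ptm_peak} entries.
#' @return A list of class \code{breath_result}: \code{$ventilation}
#'   (per-unit delivered volume, mL), \code{$ptm_peak} (per-airway cmH2O),
#'   \code{$inlet_pressure} (cmH2O trace), \code{$total_inspired} (mL),
#'   \code{$ptm_trace} (matrix, possibly 0-column), and \code{$units} (the
#'   updated terminal-unit state for chaining breaths).
#' @export
simulate_breath <- function(tree, radii, spec = breath_spec(),
                            units = terminal_units(tree),
                            params = wall_params(),
                            trace_airways = integer(0)) {
  stopifnot(inherits(tree, "airway_tree"),
            length(radii) == tree$n_airways,
            all(radii > 0),
            all(trace_airways >= 1), all(trace_airways <= tree$n_airways))
  n_steps <- round(spec$duration / spec$dt)
  n_insp <- round(n_steps * spec$insp_fraction)
  Rres <- airway_resistance(radii, tree$airways$length, spec$viscosity)
  Q <- spec$tidal_volume / (n_insp * spec$dt)
  res <- breath_core(tree$generations, Rres, units$C_unit, spec$dt,
                     n_insp, n_steps - n_insp, Q,
                     params$tau, params$P_el0, units$V, spec$peep,
                     as.integer(trace_airways) - 1L)
  units$V <- res$V_end
  structure(list(ventilation = res$ventilation,
                 ptm_peak = res$ptm_peak,
                 inlet_pressure = res$inlet_pressure,
                 total_inspired = res$total_inspired,
                 ptm_trace = res$ptm_trace,
                 units = units),
            class = "breath_result")
}
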