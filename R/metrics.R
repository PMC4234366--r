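#' Fraction of closed terminal units
#'
#' A terminal unit counts as closed (severely hypoventilated) when its
#' delivered volume falls below a threshold fraction (default 15%) of the
#' average ventilation per unit in the same breath. The index is invariant
#' to uniform rescaling of the ventilation vector.
#'
#' @param ventilation Per-unit delivered volumes (mL). Marginally negative
#'   values (gas-trapped units losing volume to neighbours during
#'   inspiration) are allowed and always count as closed; the mean is taken
#'   over volumes floored at zero.
#' @param threshold Fraction of the mean ventilation (default 0.15).
#' @return Fraction of units below threshold, in [0, 1].
#' @export
closed_fraction <- function(ventilation, threshold = 0.15) {
  stopifnot(length(ventilation) >= 1, all(is.finite(ventilation)))
  m <- mean(pmax(ventilation, 0))
  if (m <= 0) {
    warning("all-zero ventilation: every unit counted as closed")
    return(1)
  }
  mean(ventilation < threshold * m)
}

#' Mean closed fraction over the last complete DI cycle
#'
#' \eqn{F_{c,mean}} is the arithmetic mean of the per-breath closed
#' fractions over the breaths of the last complete DI cycle in the run. For
#' schedules without DIs (\code{ratio = 1}) the degenerate-cycle convention
#' averages over the final 400 s worth of breaths instead.
#'
#' @param fc Per-breath closed fractions (or a \code{vdef_trajectory}, whose
#'   \code{$fc} is used).
#' @param schedule The [di_schedule()] that produced the run.
#' @return \eqn{F_{c,mean}} in [0, 1].
#' @export
fc_mean <- function(fc, schedule) {
  if (inherits(fc, "vdef_trajectory")) {
    if (missing(schedule)) schedule <- fc$config$schedule
    fc <- fc$fc
  }
  n_cycle <- if (schedule$ratio > 1) {
    schedule$n
  } else {
    min(length(fc), as.integer(round(400 / schedule$duration)))
  }
  K <- length(fc)
  if (K < n_cycle) stop("run does not cover a complete DI cycle")
  last_end <- (K %/% n_cycle) * n_cycle
  mean(fc[(last_end - n_cycle + 1L):last_end])
}

#' Mean-normalized ventilation map
#'
#' Places each terminal unit's ventilation, normalized by the mean over all
#' units, on the Mandelbrot-style display grid (64 x 64 for G = 12).
#'
#' @param ventilation Per-unit delivered volumes (mL).
#' @param mapping A [map_terminals_to_grid()] result matching the unit
#'   count.
#' @return A numeric matrix (class \code{ventilation_map}) whose cells
#'   average exactly 1.
#' @export
ventilation_map <- function(ventilation, mapping) {
  stopifnot(inherits(mapping, "grid_mapping"),
            length(ventilation) == nrow(mapping$cells))
  m <- mean(ventilation)
  if (m <= 0) stop("zero mean ventilation: map undefined")
  out <- matrix(NA_real_, mapping$nrow, mapping$ncol)
  out[cbind(mapping$cells$row, mapping$cells$col)] <-
    ventilation[mapping$cells$unit] / m
  class(out) <- c("ventilation_map", class(out))
  out
}

#' 6 Hz input resistance of the airway tree
#'
#' Real part of the input impedance at the airway opening. Terminal units
#' are pure compliances with impedance \eqn{-i/(\omega C)}; every airway
#' adds its Poiseuille resistance in series and sibling subtrees combine in
#' parallel, collapsed recursively from the terminal units to the trachea.
#'
#' @param tree An \code{airway_tree}.
#' @param radii Per-airway radii (cm); radii at the minimum cap contribute
#'   the capped (very large) resistance.
#' @param frequency Oscillation frequency (Hz), default 6.
#' @param compliances Per-unit compliance (mL/cmH2O): scalar or one per
#'   terminal unit.
#' @param viscosity Air dynamic viscosity (Pa s).
#' @return Resistance in cmH2O s/L.
#' @export
input_resistance <- function(tree, radii, frequency = 6, compliances,
                             viscosity = 1.81e-5) {
  stopifnot(inherits(tree, "airway_tree"), frequency > 0,
            length(radii) == tree$n_airways)
  G <- tree$generations
  omega <- 2 * pi * frequency
  Cu <- rep_len(compliances, tree$n_terminal)
  Rres <- airway_resistance(radii, tree$airways$length, viscosity)
  # terminal airways in series with their unit compliance
  gen_ids <- function(g) seq.int(2L^g, 2L^(g + 1L) - 1L)
  Z <- Rres[gen_ids(G)] + (-1i / (omega * Cu))
  if (G > 0) {
    for (g in seq.int(G - 1L, 0L)) {
      ids <- gen_ids(g)
      Z1 <- Z[seq(1L, length(Z), by = 2L)]
      Z2 <- Z[seq(2L, length(Z), by = 2L)]
      Z <- Rres[ids] + Z1 * Z2 / (Z1 + Z2)
    }
  }
  Re(Z[1L]) * 1000   # cmH2O s/mL -> cmH2O s/L
}

#' Resistance series of a trajectory
#'
#' Packages the per-breath 6 Hz resistance of a run with its fully dilated
#' reference \eqn{R_0} and the DI breath indices, for DI response analysis.
#'
#' @param traj A \code{vdef_trajectory}.
#' @return A list of class \code{resistance_series}: \code{$R} (cmH2O s/L),
#'   \code{$R0}, \code{$di_breaths}, \code{$schedule}.
#' @export
resistance_series <- function(traj) {
  stopifnot(inherits(traj, "vdef_trajectory"))
  C_unit <- traj$config$total_compliance / traj$tree$n_terminal
  R0 <- input_resistance(traj$tree, traj$r0, 6, C_unit,
                         traj$config$spec$viscosity)
  structure(list(R = traj$r6hz, R0 = R0, di_breaths = traj$di_breaths,
                 schedule = traj$config$schedule),
            class = "resistance_series")
}

#' Pre-/post-DI resistance response
#'
#' From a per-breath resistance series, extracts the resistance at the
#' breath before a DI (\eqn{R_{Pre-DI}}) and at the breath after it
#' (\eqn{R_{Post-DI}}), and forms the relative response
#' \eqn{R_{Post-DI}/R_{Pre-DI}} and, when a sweep-level \eqn{R_{min}} is
#' supplied, the normalized response
#' \eqn{R^*_{Post-DI} = (R_{Post-DI} - R_{min})/(R_{Pre-DI} - R_{min})}.
#' \eqn{R_{min}} is the minimum of the \eqn{R_{Post-DI}} values across the
#' conditions of a sweep, not a per-run quantity.
#'
#' @param series A [resistance_series()] (or a plain numeric vector of
#'   per-breath resistances, in which case \code{di_breaths} must be given).
#' @param di_breaths DI breath indices (taken from the series by default).
#' @param R_min Sweep-level minimum of post-DI resistances (optional).
#' @param which_di Which DI to evaluate: \code{"last"} (default, the stable
#'   state) or an index into the usable DIs.
#' @return A list with \code{R_pre}, \code{R_post}, \code{ratio}
#'   (= post/pre) and \code{R_post_star} (NA when \code{R_min} is absent;
#'   signaled as NA with a warning when \eqn{R_{Pre-DI} = R_{min}}).
#' @export
di_response <- function(series, di_breaths = NULL, R_min = NULL,
                        which_di = "last") {
  if (inherits(series, "resistance_series")) {
    R <- series$R
    if (is.null(di_breaths)) di_breaths <- series$di_breaths
  } else {
    R <- series
  }
  usable <- di_breaths[di_breaths > 1 & di_breaths < length(R)]
  if (length(usable) == 0) stop("no DI with both a preceding and a following breath")
  k <- if (identical(which_di, "last")) usable[length(usable)] else usable[which_di]
  R_pre <- R[k - 1L]
  R_post <- R[k + 1L]
  star <- NA_real_
  if (!is.null(R_min)) {
    if (abs(R_pre - R_min) < .Machine$double.eps * max(1, abs(R_min))) {
      warning("R_Pre-DI equals R_min: normalized response undefined")
    } else {
      star <- (R_post - R_min) / (R_pre - R_min)
    }
  }
  list(R_pre = R_pre, R_post = R_post, ratio = R_post / R_pre,
       R_post_star = star, di_breath = k)
}

#' Normalized DI interval
#'
#' The DI cycle interval rescaled by the constriction speed index,
#' \eqn{interval \times S_c / S_{c,ref}}: conditions with different
#' re-narrowing speeds collapse onto a single behavior when compared at the
#' same normalized interval.
#'
#' @param interval DI cycle interval (s).
#' @param S_c Actual constriction speed index.
#' @param S_c_ref Reference ("normal") speed index, default 0.05.
#' @return Normalized interval (s).
#' @export
normalized_interval <- function(interval, S_c, S_c_ref = 0.05) {
  stopifnot(S_c_ref > 0)
  interval * S_c / S_c_ref
}
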