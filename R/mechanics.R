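#' Airway wall / smooth-muscle model parameters
#'
#' Parameters of the single-airway constitutive law. The wall balance at a
#' relative radius \eqn{\rho = r/r_0} equates the applied peak transmural
#' pressure with the wall pressure
#' \deqn{G(\rho) = P_{pass}(\rho) + P_a T_r w f(\rho)/\rho,}
#' a sigmoidal passive recoil plus a Laplace-type active pressure with a
#' Gaussian force-length factor \eqn{f} peaking at \eqn{\rho = 1}. With the
#' default constants the wall pressure is non-monotone at high activation:
#' over a mid-range band of transmural pressures an airway can rest either on
#' an open branch or collapsed at the minimum-radius cap, the bistability
#' that lets ventilation defects emerge. The constants are calibrated so that
#' this band overlaps the peak transmural pressures of tidal breathing at the
#' default ventilation; they are a documented model choice, not measured
#' values.
#'
#' @param rho_max Maximal relative radius \eqn{r_{max}/r_0} (dimensionless).
#'   The passive law saturates steeply as \eqn{\rho \to \rho_{max}}.
#' @param k_collapse Compressive stiffness scale (cmH2O) of the
#'   \eqn{1 - 1/\rho} passive term resisting narrowing.
#' @param k_stiff Stiffness scale (cmH2O) of the saturation term that pins
#'   the fully dilated radius near \eqn{\rho = 1} under physiologic loads.
#' @param m_sat Exponent of the saturation term; large values confine its
#'   influence to \eqn{\rho \gtrsim 0.8} so that compressive behaviour is
#'   governed by \code{k_collapse} alone.
#' @param P_a Active pressure scale (cmH2O): pressure equivalent of maximal
#'   smooth-muscle tension at the reference radius (\eqn{T_r = 1, w = 1,
#'   \rho = 1}).
#' @param sigma_f Width (dimensionless) of the Gaussian force-length factor
#'   \eqn{f(\rho) = \exp(-(\rho-1)^2 / 2\sigma_f^2)}.
#' @param tau Parenchymal tethering amplification (dimensionless), applied by
#'   the breath solver to regional expansion deviations.
#' @param P_el0 Elastic recoil pressure at PEEP (cmH2O); baseline outward
#'   traction on every airway at end expiration.
#' @param r_min_rel Minimum relative radius cap; an airway at the cap is
#'   functionally closed but keeps a finite (very large) resistance.
#' @return A list of class \code{wall_params}.
#' @export
wall_params <- function(rho_max = 1.02,
                        k_collapse = 2,
                        k_stiff = 4,
                        m_sat = 7,
                        P_a = 56,
                        sigma_f = 0.42,
                        tau = 1.5,
                        P_el0 = 5,
                        r_min_rel = 0.01) {
  p <- list(rho_max = rho_max, k_collapse = k_collapse, k_stiff = k_stiff,
            m_sat = m_sat, P_a = P_a, sigma_f = sigma_f, tau = tau,
            P_el0 = P_el0, r_min_rel = r_min_rel)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))),
            rho_max > 1, r_min_rel < 1)
  class(p) <- "wall_params"
  p
}

#' Passive transmural pressure of the airway wall
#'
#' Strictly increasing in the relative radius, zero at the fully dilated
#' radius (\eqn{\rho = 1}) and saturating steeply as \eqn{\rho} approaches
#' \eqn{\rho_{max}}:
#' \deqn{P_{pass}(\rho) = k_c (1 - 1/\rho) + k_s (h(\rho) - h(1)), \quad
#'   h(\rho) = \frac{x^m}{1 - x^m}, \; x = \rho/\rho_{max}.}
#' The \eqn{1 - 1/\rho} term is the soft compressive recoil; the high-power
#' logistic term contributes only near full dilation, where it diverges at
#' \eqn{\rho_{max}}.
#'
#' @param r_rel Relative radius \eqn{r/r_0}, in \eqn{(0, \rho_{max})}.
#' @param params A [wall_params()] object.
#' @return Pressure in cmH2O (vectorized over \code{r_rel}).
#' @export
passive_pressure <- function(r_rel, params = wall_params()) {
  if (any(r_rel <= 0 | r_rel >= params$rho_max)) {
    stop("r_rel must lie in (0, rho_max)")
  }
  h <- function(rho) {
    xm <- (rho / params$rho_max)^params$m_sat
    xm / (1 - xm)
  }
  params$k_collapse * (1 - 1 / r_rel) + params$k_stiff * (h(r_rel) - h(1))
}

#' Active (smooth-muscle) transmural pressure
#'
#' Laplace-type pressure generated by circumferential smooth-muscle tension,
#' proportional to the activation \code{T_r} and the wall-thickness factor
#' \code{w}, with a unimodal force-length factor peaking at the fully dilated
#' radius:
#' \deqn{P_{act}(\rho) = P_a T_r w \exp(-(\rho-1)^2/2\sigma_f^2) / \rho.}
#'
#' @param r_rel Relative radius \eqn{r/r_0} (> 0).
#' @param T_r Relative smooth-muscle activation in \eqn{[0, 1]}
#'   (1 = maximal stimulation).
#' @param w Wall-thickness factor (> 0).
#' @param params A [wall_params()] object.
#' @return Pressure in cmH2O.
#' @export
active_pressure <- function(r_rel, T_r, w = 1, params = wall_params()) {
  if (any(T_r < 0)) stop("T_r must be non-negative")
  if (any(w <= 0)) stop("w must be positive")
  if (any(r_rel <= 0)) stop("r_rel must be positive")
  params$P_a * T_r * w *
    exp(-(r_rel - 1)^2 / (2 * params$sigma_f^2)) / r_rel
}

# Active shape factor f(rho)/rho; active pressure = P_a*T_r*w * shape.
active_shape <- function(r_rel, params) {
  exp(-(r_rel - 1)^2 / (2 * params$sigma_f^2)) / r_rel
}

# Total wall pressure G(rho) for activation amplitude A = P_a*T_r*w.
wall_pressure <- function(r_rel, A, params) {
  passive_pressure(r_rel, params) + A * active_shape(r_rel, params)
}

# Vectorized steady-state relative radius solver.
#
# For each element solves G(rho) = P for the stable root (G increasing) in
# whose basin the current radius lies: a narrowing airway (G(rho_cur) > P)
# relaxes to the nearest stable root below its current radius, a dilating
# one to the nearest stable root above. When no stable root exists in that
# direction the radius is pinned at the attracting boundary (the cap when
# narrowing, the maximal radius when dilating). Returns list(rho, boundary)
# where boundary flags cap/rho_max returns.
solve_rstar_rel <- function(P, A, rho_cur, params,
                            n_grid = 240L, iters = 52L) {
  n <- length(P)
  stopifnot(length(A) == n, length(rho_cur) == n)
  lo_lim <- params$r_min_rel
  hi_lim <- params$rho_max - 1e-9 * (params$rho_max - 1)
  grid <- seq(lo_lim, params$rho_max - 1e-4, length.out = n_grid)
  g0 <- passive_pressure(grid, params)
  g1 <- active_shape(grid, params)
  # H[k, i] = G_i(grid[k]) - P_i
  H <- outer(g1, A) + g0
  H <- sweep(H, 2L, P)
  neg <- H < 0
  up <- neg[-n_grid, , drop = FALSE] & !neg[-1L, , drop = FALSE]
  cur_idx <- findInterval(rho_cur, grid, all.inside = TRUE)
  H_cur <- g0_at(rho_cur, params) + A * active_shape(rho_cur, params) - P
  narrowing <- H_cur >= 0
  # crossings are sparse (at most a few per airway): extract them and pick
  # the nearest stable crossing below (narrowing) / above (dilating) the
  # current radius. which() returns column-major order, so rows ascend
  # within each column and indexed overwrite keeps the last (= largest) row
  # per column.
  pick_below <- integer(n)
  pick_above <- integer(n)
  idx <- which(up)
  if (length(idx)) {
    rows <- (idx - 1L) %% (n_grid - 1L) + 1L
    cols <- (idx - 1L) %/% (n_grid - 1L) + 1L
    # a crossing in the bracket containing the current radius serves both
    # directions
    bm <- which(rows <= cur_idx[cols])
    pick_below[cols[bm]] <- rows[bm]
    am <- which(rows >= cur_idx[cols])
    pick_above[rev(cols[am])] <- rev(rows[am])
  }
  pick <- ifelse(narrowing, pick_below, pick_above)
  has_root <- pick > 0L
  pick[!has_root] <- 1L
  lo <- grid[pick]
  hi <- grid[pick + 1L]
  if (any(has_root)) {
    idx <- which(has_root)
    loi <- lo[idx]; hii <- hi[idx]
    Ai <- A[idx]; Pi <- P[idx]
    for (k in seq_len(iters)) {
      mid <- 0.5 * (loi + hii)
      Hmid <- passive_pressure(mid, params) + Ai * active_shape(mid, params) - Pi
      below <- Hmid < 0
      loi[below] <- mid[below]
      hii[!below] <- mid[!below]
    }
    lo[idx] <- 0.5 * (loi + hii)
  }
  rho <- lo
  boundary <- !has_root
  if (any(boundary)) {
    rho[boundary] <- ifelse(narrowing[boundary], lo_lim, hi_lim)
  }
  list(rho = rho, boundary = boundary)
}

# passive_pressure tolerant of values pinned exactly at the cap or rho_max
g0_at <- function(rho, params) {
  passive_pressure(pmin(pmax(rho, params$r_min_rel),
                        params$rho_max - 1e-9 * (params$rho_max - 1)),
                   params)
}

#' Predicted steady-state radius for a peak transmural pressure
#'
#' Solves the wall balance
#' \eqn{P_{pass}(\rho) + P_{act}(\rho; T_r, w) = P_{tm}} for a stable
#' equilibrium (wall pressure increasing in \eqn{\rho}). Under high
#' activation the balance can have two stable states; the root on the same
#' branch as -- i.e. nearest to -- the airway's current radius is returned,
#' which realizes the history dependence of the breath-to-breath dynamics.
#' When no interior root exists the radius is pushed to the nearer attracting
#' boundary (the minimum-radius cap for a dominating wall pressure, the
#' maximal radius otherwise).
#'
#' @param P_tm_peak Peak transmural pressure of the preceding breath (cmH2O);
#'   vectorized.
#' @param T_r Relative smooth-muscle activation in \eqn{[0, 1]}.
#' @param r0 Fully dilated radius (cm), vectorized like \code{P_tm_peak}.
#' @param w Wall-thickness factor(s).
#' @param r_current Current radius (cm); branch selector under bistability.
#'   Defaults to \code{r0}.
#' @param params A [wall_params()] object.
#' @return Steady-state radius r* in cm.
#' @export
steady_state_radius <- function(P_tm_peak, T_r, r0, w = 1,
                                r_current = r0, params = wall_params()) {
  stopifnot(all(is.finite(P_tm_peak)), T_r >= 0)
  n <- length(P_tm_peak)
  r0 <- rep_len(r0, n); w <- rep_len(w, n); r_current <- rep_len(r_current, n)
  A <- params$P_a * T_r * w
  sol <- solve_rstar_rel(P_tm_peak, A, pmin(pmax(r_current / r0,
                                                 params$r_min_rel),
                                            params$rho_max - 1e-6),
                         params)
  sol$rho * r0
}

#' Scan stable wall equilibria over a grid of transmural pressures
#'
#' Diagnostic for the bistability of the constitutive law: for each pressure
#' on the grid, lists every stable equilibrium relative radius. Interior
#' equilibria are stable roots of the wall balance; the minimum-radius cap
#' counts as a (collapsed) stable state whenever the wall pressure at the cap
#' exceeds the applied pressure, since the dynamics then pin the radius
#' there.
#'
#' @param T_r Relative smooth-muscle activation.
#' @param w Wall-thickness factor.
#' @param P_grid Ascending grid of transmural pressures (cmH2O).
#' @param params A [wall_params()] object.
#' @param residual_tol Balance-residual tolerance (cmH2O) each listed
#'   interior equilibrium must satisfy.
#' @return A list of class \code{equilibrium_scan} with \code{$P_grid},
#'   \code{$equilibria} (list of numeric vectors of stable relative radii)
#'   and \code{$counts}.
#' @export
bistability_scan <- function(T_r, w = 1, P_grid = seq(0, 40, by = 0.25),
                             params = wall_params(), residual_tol = 1e-8) {
  stopifnot(!is.unsorted(P_grid))
  A <- params$P_a * T_r * w
  n_grid <- 2000L
  grid <- seq(params$r_min_rel, params$rho_max - 1e-4, length.out = n_grid)
  Gv <- wall_pressure(grid, A, params)
  eq <- lapply(P_grid, function(P) {
    H <- Gv - P
    up <- which(H[-n_grid] < 0 & H[-1L] >= 0)
    roots <- vapply(up, function(k) {
      lo <- grid[k]; hi <- grid[k + 1L]
      for (it in 1:60) {
        mid <- 0.5 * (lo + hi)
        if (wall_pressure(mid, A, params) - P < 0) lo <- mid else hi <- mid
      }
      0.5 * (lo + hi)
    }, numeric(1))
    roots <- roots[abs(wall_pressure(roots, A, params) - P) < residual_tol]
    if (H[1L] >= 0) roots <- c(params$r_min_rel, roots)
    roots
  })
  structure(list(P_grid = P_grid, equilibria = eq,
                 counts = lengths(eq), T_r = T_r, w = w),
            class = "equilibrium_scan")
}

#' Export steady-state radius curves to CSV
#'
#' Writes \eqn{r^*/r_0} as a function of peak transmural pressure for a set
#' of activation levels, one row per (T_r, P_tm) pair, for inspection of the
#' shipped constitutive parameterization. Both stable branches are exported
#' where the law is bistable (columns \code{rho_open}, \code{rho_collapsed}).
#'
#' @param path Output CSV path.
#' @param T_r_values Activation levels to scan.
#' @param P_grid Pressure grid (cmH2O).
#' @param params A [wall_params()] object.
#' @return Invisibly, the exported data frame.
#' @export
export_rstar_curves <- function(path, T_r_values = c(0, 0.6, 0.9, 1),
                                P_grid = seq(0, 40, by = 0.5),
                                params = wall_params()) {
  rows <- do.call(rbind, lapply(T_r_values, function(Tr) {
    sc <- bistability_scan(Tr, 1, P_grid, params)
    data.frame(
      T_r = Tr,
      P_tm = P_grid,
      rho_open = vapply(sc$equilibria, function(e)
        if (length(e)) max(e) else NA_real_, numeric(1)),
      rho_collapsed = vapply(sc$equilibria, function(e)
        if (length(e) > 1) min(e) else NA_real_, numeric(1)),
      n_stable = sc$counts
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
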