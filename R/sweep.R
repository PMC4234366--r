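#' Build a sweep grid of DI conditions
#'
#' Crosses DI cycle intervals and relative DI volumes with activation
#' levels, constriction speed indexes and seeds into one condition table,
#' one row per run. The short-interval study group is
#' \code{intervals = c(25, 50, 100, 200, 400)} crossed with
#' \code{ratios = seq(1.2, 3, by = 0.2)}; the long-interval group is
#' \code{intervals = c(400, 800, 1600)} with \code{ratios = 3:6}.
#'
#' @param intervals DI cycle intervals (s).
#' @param ratios Relative DI volumes \eqn{V_{DI}/V_T}.
#' @param T_r Activation levels.
#' @param S_c Constriction speed indexes.
#' @param seeds Distinct integer seeds (one run per seed per condition).
#' @param generations Tree scale for every run in the sweep.
#' @return A data.frame of class \code{sweep_grid}.
#' @export
sweep_grid <- function(intervals, ratios, T_r = 1, S_c = 0.05,
                       seeds = 1L, generations = 8L) {
  stopifnot(length(intervals) >= 1, length(ratios) >= 1,
            !anyDuplicated(seeds))
  g <- expand.grid(interval = intervals, ratio = ratios, T_r = T_r,
                   S_c = S_c, seed = as.integer(seeds),
                   KEEP.OUT.ATTRS = FALSE)
  g$generations <- as.integer(generations)
  class(g) <- c("sweep_grid", class(g))
  g
}

#' Run a sweep of simulation conditions
#'
#' Runs one simulation per grid row and aggregates the outcome measures.
#' Runs are independent (results do not depend on execution order); a
#' failing run is isolated, reported in the \code{error} column and does not
#' abort the sweep.
#'
#' @param grid A [sweep_grid()] (or any data.frame with columns
#'   \code{interval}, \code{ratio}, \code{T_r}, \code{S_c}, \code{seed},
#'   \code{generations}).
#' @param base_config A [sim_config()] supplying everything the grid does
#'   not vary (breath spec, wall params, breath count, cv, ...).
#' @param keep_trajectories Keep the full trajectories (memory-heavy; needed
#'   for map/trace figures).
#' @param progress Print one line per completed run.
#' @return A list of class \code{vdef_sweep}: \code{$results} (one row per
#'   run: condition, \code{fc_mean}, \code{R0}, \code{R_pre}, \code{R_post},
#'   \code{norm_interval}, \code{error}) and \code{$trajectories} (list or
#'   NULL).
#' @export
run_sweep <- function(grid, base_config = sim_config(),
                      keep_trajectories = FALSE, progress = FALSE) {
  if (nrow(grid) == 0) {
    empty <- data.frame(interval = numeric(0), ratio = numeric(0),
                        T_r = numeric(0), S_c = numeric(0),
                        seed = integer(0), generations = integer(0),
                        fc_mean = numeric(0), R0 = numeric(0),
                        R_pre = numeric(0), R_post = numeric(0),
                        norm_interval = numeric(0), error = character(0))
    return(structure(list(results = empty, trajectories = NULL, grid = grid),
                     class = "vdef_sweep"))
  }
  rows <- vector("list", nrow(grid))
  trajs <- if (keep_trajectories) vector("list", nrow(grid)) else NULL
  for (i in seq_len(nrow(grid))) {
    cond <- grid[i, ]
    row <- data.frame(interval = cond$interval, ratio = cond$ratio,
                      T_r = cond$T_r, S_c = cond$S_c, seed = cond$seed,
                      generations = cond$generations,
                      fc_mean = NA_real_, R0 = NA_real_,
                      R_pre = NA_real_, R_post = NA_real_,
                      norm_interval = normalized_interval(cond$interval,
                                                          cond$S_c),
                      error = NA_character_)
    res <- tryCatch({
      cfg <- base_config
      cfg$generations <- cond$generations
      cfg$T_r <- cond$T_r
      cfg$S_c <- cond$S_c
      cfg$seed <- cond$seed
      cfg$schedule <- di_schedule(cond$interval, cond$ratio,
                                  base_config$schedule$duration,
                                  base_config$schedule$mean_volume)
      traj <- run_simulation(cfg)
      row$fc_mean <- fc_mean(traj)
      rs <- resistance_series(traj)
      row$R0 <- rs$R0
      if (length(rs$di_breaths) > 0) {
        dr <- di_response(rs)
        row$R_pre <- dr$R_pre
        row$R_post <- dr$R_post
      }
      traj
    }, error = function(e) {
      row$error <<- conditionMessage(e)
      NULL
    })
    if (keep_trajectories) trajs[[i]] <- res
    rows[[i]] <- row
    if (progress) {
      message(sprintf("[%d/%d] interval=%g ratio=%g T_r=%g S_c=%g seed=%d: Fc,mean=%s",
                      i, nrow(grid), cond$interval, cond$ratio, cond$T_r,
                      cond$S_c, cond$seed,
                      format(row$fc_mean, digits = 3)))
    }
  }
  structure(list(results = do.call(rbind, rows), trajectories = trajs,
                 grid = grid),
            class = "vdef_sweep")
}

#' Summarize a sweep over seeds
#'
#' Mean, minimum and maximum of \eqn{F_{c,mean}} per condition across the
#' random wall-thickness realizations (the range shown as error bars in
#' multi-seed condition plots).
#'
#' @param sweep A \code{vdef_sweep}.
#' @return A data.frame with one row per (interval, ratio, T_r, S_c).
#' @export
summarize_sweep <- function(sweep) {
  res <- sweep$results
  agg <- stats::aggregate(fc_mean ~ interval + ratio + T_r + S_c, data = res,
                          FUN = function(x) c(mean = mean(x), min = min(x),
                                              max = max(x)),
                          na.action = stats::na.omit)
  out <- cbind(agg[, c("interval", "ratio", "T_r", "S_c")],
               as.data.frame(agg$fc_mean))
  names(out)[5:7] <- c("fc_mean", "fc_min", "fc_max")
  out
}

#' Plot a ventilation map
#'
#' @param x A [ventilation_map()] matrix.
#' @param zlim Shared color scale (default 0-1.85, the scale used across all
#'   map panels).
#' @param ... Passed to [graphics::image()].
#' @export
plot.ventilation_map <- function(x, zlim = c(0, 1.85), ...) {
  z <- t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE]
  graphics::image(z, zlim = zlim, axes = FALSE, asp = nrow(x) / ncol(x),
                  col = grDevices::hcl.colors(64, "Inferno"), ...)
  invisible(x)
}

#' Render figure files from a sweep
#'
#' Writes PNG figures: \eqn{F_{c,mean}} versus relative DI volume, one curve
#' per interval; the same data against the normalized DI interval (the
#' speed-index collapse plot); and, when trajectories were kept, a matrix of
#' ventilation maps and a matrix of relative-radius traces for the traced
#' terminal airways, all map panels sharing the 0-1.85 color scale.
#'
#' @param sweep A \code{vdef_sweep}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written (none for an empty
#'   sweep).
#' @export
render_figures <- function(sweep, dir = ".") {
  res <- sweep$results
  res <- res[is.na(res$error) & !is.na(res$fc_mean), , drop = FALSE]
  if (nrow(res) == 0) return(invisible(character(0)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f1 <- file.path(dir, "fc_mean_vs_ratio.png")
  grDevices::png(f1, width = 900, height = 650)
  intervals <- sort(unique(res$interval))
  cols <- grDevices::hcl.colors(max(2L, length(intervals)), "Dark 3")
  graphics::plot(NULL, xlim = range(res$ratio), ylim = c(0, max(res$fc_mean, 0.05)),
                 xlab = "V_DI / V_T", ylab = "F_c,mean")
  for (j in seq_along(intervals)) {
    sub <- summarize_sweep(sweep)
    sub <- sub[sub$interval == intervals[j], ]
    sub <- sub[order(sub$ratio), ]
    graphics::lines(sub$ratio, sub$fc_mean, type = "b", col = cols[j], pch = 16)
    rng <- sub$fc_max > sub$fc_min
    if (any(rng)) {
      graphics::arrows(sub$ratio[rng], sub$fc_min[rng], sub$ratio[rng],
                       sub$fc_max[rng], angle = 90, code = 3, length = 0.02,
                       col = cols[j])
    }
  }
  graphics::legend("topright", legend = paste(intervals, "s"),
                   col = cols[seq_along(intervals)], lty = 1, pch = 16)
  grDevices::dev.off()
  files <- c(files, f1)

  if (length(unique(res$S_c)) > 1) {
    f2 <- file.path(dir, "fc_mean_vs_normalized_interval.png")
    grDevices::png(f2, width = 900, height = 650)
    scs <- sort(unique(res$S_c))
    graphics::plot(NULL, xlim = range(res$norm_interval),
                   ylim = c(0, max(res$fc_mean, 0.05)), log = "x",
                   xlab = "normalized DI interval (s)", ylab = "F_c,mean")
    for (j in seq_along(scs)) {
      sub <- res[res$S_c == scs[j], ]
      for (rt in unique(sub$ratio)) {
        s2 <- sub[sub$ratio == rt, ]
        s2 <- s2[order(s2$norm_interval), ]
        graphics::lines(s2$norm_interval, s2$fc_mean, type = "b",
                        lty = j, pch = j, col = "gray20")
      }
    }
    graphics::legend("topleft", legend = paste("S_c =", scs), lty = seq_along(scs))
    grDevices::dev.off()
    files <- c(files, f2)
  }

  if (!is.null(sweep$trajectories)) {
    keep <- !vapply(sweep$trajectories, is.null, logical(1))
    if (any(keep)) {
      trajs <- sweep$trajectories[keep]
      nc <- ceiling(sqrt(length(trajs)))
      nr <- ceiling(length(trajs) / nc)
      f3 <- file.path(dir, "ventilation_maps.png")
      grDevices::png(f3, width = 300 * nc, height = 300 * nr)
      graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
      for (tr in trajs) {
        mp <- map_terminals_to_grid(tr$tree)
        vm <- ventilation_map(tr$ventilation[nrow(tr$ventilation), ], mp)
        plot(vm, main = sprintf("ratio %g, %g s", tr$config$schedule$ratio,
                                tr$config$schedule$interval))
      }
      grDevices::dev.off()
      f4 <- file.path(dir, "radii_traces.png")
      grDevices::png(f4, width = 300 * nc, height = 300 * nr)
      graphics::par(mfrow = c(nr, nc), mar = c(2, 2, 2, 1))
      for (tr in trajs) {
        t_s <- seq_len(nrow(tr$radii_trace)) * tr$config$schedule$duration
        graphics::matplot(t_s, tr$radii_trace, type = "l", lty = 1,
                          col = grDevices::gray.colors(ncol(tr$radii_trace),
                                                       0.1, 0.7),
                          ylim = c(0, 1.05), xlab = "time (s)",
                          ylab = "r/r0",
                          main = sprintf("ratio %g, %g s",
                                         tr$config$schedule$ratio,
                                         tr$config$schedule$interval))
      }
      grDevices::dev.off()
      files <- c(files, f3, f4)
    }
  }
  invisible(files)
}
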