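p_default <- wall_params()

test_that("passive law: zero at full dilation, increasing, steep saturation", {
  expect_identical(passive_pressure(1, p_default), 0)
  rho <- seq(0.02, p_default$rho_max - 1e-4, length.out = 400)
  expect_true(all(diff(passive_pressure(rho, p_default)) > 0))
  expect_gt(passive_pressure(p_default$rho_max - 1e-4, p_default), 100)
  expect_error(passive_pressure(0, p_default), "r_rel")
  expect_error(passive_pressure(p_default$rho_max, p_default), "r_rel")
})

test_that("passive law matches an independent evaluation at the midpoint", {
  # direct arithmetic from the documented form, written out longhand
  p <- p_default
  x_mid <- (0.5 / p$rho_max)^p$m_sat
  x_one <- (1 / p$rho_max)^p$m_sat
  expected <- p$k_collapse * (1 - 1 / 0.5) +
    p$k_stiff * (x_mid / (1 - x_mid) - x_one / (1 - x_one))
  expect_equal(passive_pressure(0.5, p), expected)
})

test_that("active law: proportional to T_r and w, normalized at the peak", {
  expect_identical(active_pressure(c(0.3, 1, 0.9), 0, 1, p_default),
                   c(0, 0, 0))
  a1 <- active_pressure(0.7, 0.5, 1, p_default)
  expect_equal(active_pressure(0.7, 0.5, 2, p_default), 2 * a1)
  expect_equal(active_pressure(0.7, 1, 1, p_default), 2 * a1)
  # shape factor is exactly 1 at the force-length peak
  expect_equal(active_pressure(1, 1, 1, p_default), p_default$P_a)
  expect_error(active_pressure(0.5, -0.1, 1, p_default), "T_r")
  expect_error(active_pressure(0.5, 1, 0, p_default), "w")
})

test_that("steady state: passive airway at zero load returns r0; saturation", {
  expect_equal(steady_state_radius(0, 0, r0 = 0.25, w = 1), 0.25,
               tolerance = 1e-9)
  expect_gt(steady_state_radius(500, 0, r0 = 0.25), 0.25 * 1.015)
  expect_lt(steady_state_radius(500, 0, r0 = 0.25), 0.25 * p_default$rho_max)
})

test_that("high activation yields two stable roots over a pressure interval", {
  # brute-force enumeration oracle on a fine radius grid
  rho <- seq(p_default$r_min_rel, p_default$rho_max - 1e-4,
             length.out = 6000)
  G <- passive_pressure(rho, p_default) +
    active_pressure(rho, 1, 1, p_default)
  n_stable <- vapply(seq(2, 35, by = 0.5), function(P) {
    H <- G - P
    sum(H[-length(H)] < 0 & H[-1] >= 0) + as.integer(H[1] >= 0)
  }, integer(1))
  expect_true(any(n_stable == 2))
  two <- which(n_stable == 2)
  expect_equal(two, seq(min(two), max(two)))   # contiguous interval
})

test_that("branch selection follows the current radius; residual is tiny", {
  P_bist <- 18   # inside the bistable band at T_r = 1
  r_low <- steady_state_radius(P_bist, 1, 1, 1, r_current = 0.02)
  r_high <- steady_state_radius(P_bist, 1, 1, 1, r_current = 1)
  expect_lt(r_low, 0.2)
  expect_gt(r_high, 0.3)
  resid <- abs(passive_pressure(r_high, p_default) +
                 active_pressure(r_high, 1, 1, p_default) - P_bist)
  expect_lt(resid, 1e-8)
  for (P in c(2, 5, 12, 16, 22)) {
    r <- steady_state_radius(P, 0.8, 1, 1, r_current = 1)
    resid <- abs(passive_pressure(r, p_default) +
                   active_pressure(r, 0.8, 1, p_default) - P)
    expect_lt(resid, 1e-8)
  }
})

test_that("r* is monotone: non-decreasing in P_tm, non-increasing in T_r", {
  P <- seq(16, 30, by = 0.5)
  r_open <- steady_state_radius(P, 1, rep(1, length(P)),
                                r_current = rep(1, length(P)))
  expect_true(all(diff(r_open) >= -1e-12))
  Tr <- seq(0, 1, by = 0.05)
  r_tr <- vapply(Tr, function(t)
    steady_state_radius(15, t, 1, 1, r_current = 1), numeric(1))
  expect_true(all(diff(r_tr) <= 1e-12))
})

test_that("equilibrium scan: passive monotone, activation-dependent window", {
  Pg <- seq(0, 140, by = 0.25)   # spans the full bistable band at T_r = 1
  s0 <- bistability_scan(0, 1, Pg)
  expect_true(all(s0$counts == 1))
  s1 <- bistability_scan(1, 1, Pg)
  expect_true(all(s1$counts %in% c(1L, 2L)))
  b1 <- Pg[s1$counts == 2]
  expect_gt(length(b1), 0)
  expect_equal(which(s1$counts == 2),
               seq(min(which(s1$counts == 2)), max(which(s1$counts == 2))))
  s9 <- bistability_scan(0.9, 1, Pg)
  b9 <- Pg[s9$counts == 2]
  expect_lt(length(b9), length(b1))   # narrower (possibly empty) window
})

test_that("calibration: the bistable band overlaps tidal peak pressures", {
  tr <- build_tree(6)
  br <- simulate_breath(tr, tr$airways$r0, breath_spec(),
                        terminal_units(tr), p_default)
  ptm <- range(br$ptm_peak)
  s1 <- bistability_scan(1, 1, seq(0, 60, by = 0.25), p_default)
  band <- range(s1$P_grid[s1$counts == 2])
  expect_lt(band[1], ptm[2])
  expect_gt(band[2], ptm[1])
})

test_that("r* curve export writes both branches", {
  f <- tempfile(fileext = ".csv")
  out <- export_rstar_curves(f, T_r_values = c(0, 1),
                             P_grid = seq(0, 30, by = 1))
  expect_true(file.exists(f))
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 2 * 31)
  expect_true(all(is.na(back$rho_collapsed[back$T_r == 0])))
  expect_true(any(!is.na(back$rho_collapsed[back$T_r == 1])))
})
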