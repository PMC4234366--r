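test_that("closed fraction: direct arithmetic and scale invariance", {
  expect_equal(closed_fraction(rep(2, 10)), 0)
  expect_equal(closed_fraction(c(0.1, 1, 1, 1)), 0.25)
  expect_equal(closed_fraction(c(1, 0, 0, 0)), 0.75)
  v <- runif(50)
  expect_equal(closed_fraction(v), closed_fraction(v * 123.4))
  expect_warning(fc <- closed_fraction(rep(0, 4)), "closed")
  expect_equal(fc, 1)
})

test_that("F_c,mean averages the last complete DI cycle", {
  s5 <- di_schedule(25, 2)
  expect_equal(fc_mean(rep(0.2, 10), s5), 0.2)
  expect_equal(fc_mean(c(0, 0.1, 0.2, 0.3, 0.4), s5), 0.2)
  # last complete cycle only: 12 breaths of 5-breath cycles -> breaths 6..10
  fc <- c(rep(1, 5), rep(0.4, 5), 1, 1)
  expect_equal(fc_mean(fc, s5), 0.4)
  expect_error(fc_mean(c(0.1, 0.2), s5), "complete")
  # degenerate no-DI convention: final 400 s window
  s_no <- di_schedule(400, 1)
  fc2 <- c(rep(1, 80), rep(0.25, 80))
  expect_equal(fc_mean(fc2, s_no), 0.25)
})

test_that("ventilation maps normalize to mean 1 on the display grid", {
  tr <- build_tree(4)
  mp <- map_terminals_to_grid(tr)
  vm <- ventilation_map(rep(3.3, 16), mp)
  expect_equal(unclass(vm), matrix(1, 4, 4), ignore_attr = TRUE)
  v <- runif(16)
  vm2 <- ventilation_map(v, mp)
  expect_equal(mean(vm2), 1, tolerance = 1e-12)
  expect_true(all(vm2 >= 0))
  expect_error(ventilation_map(rep(0, 16), mp), "zero mean")
  mp12 <- map_terminals_to_grid(build_tree(12))
  expect_equal(dim(ventilation_map(runif(4096), mp12)), c(64L, 64L))
})

test_that("input resistance: closed forms on one- and two-level trees", {
  tr0 <- build_tree(0)
  R_aw <- airway_resistance(tr0$airways$r0, tr0$airways$length)
  expect_equal(input_resistance(tr0, tr0$airways$r0, 6, 1),
               R_aw * 1000, tolerance = 1e-12)
  tr1 <- build_tree(1)
  Rres <- airway_resistance(tr1$airways$r0, tr1$airways$length)
  omega <- 2 * pi * 6
  Z_child <- Rres[2] + (-1i / (omega * 0.5))
  expect_equal(input_resistance(tr1, tr1$airways$r0, 6, 0.5),
               (Rres[1] + Re(Z_child) / 2) * 1000, tolerance = 1e-12)
})

test_that("recursive impedance equals the dense nodal-admittance oracle", {
  set.seed(11)
  for (G in 0:5) {
    tr <- build_tree(G)
    radii <- tr$airways$r0 * runif(tr$n_airways, 0.1, 1)
    Cu <- runif(tr$n_terminal, 0.2, 0.6)
    for (f in c(6, 1, 20)) {
      oracle <- Re(nodal_impedance(tr, radii, f, Cu)) * 1000
      expect_equal(input_resistance(tr, radii, f, Cu), oracle,
                   tolerance = 1e-9)
    }
  }
})

test_that("opening any single airway cannot raise total resistance", {
  tr <- build_tree(4)
  set.seed(3)
  radii <- tr$airways$r0 * runif(tr$n_airways, 0.2, 0.9)
  base <- input_resistance(tr, radii, 6, 0.4)
  for (j in seq_len(tr$n_airways)) {
    r2 <- radii
    r2[j] <- r2[j] * 1.25
    expect_lte(input_resistance(tr, r2, 6, 0.4), base + 1e-12)
  }
})

test_that("DI response arithmetic follows the printed definitions", {
  R <- c(9, 10, 3, 6, 7)        # DI at breath 3
  dr <- di_response(R, di_breaths = 3, R_min = 4)
  expect_equal(dr$R_pre, 10)
  expect_equal(dr$R_post, 6)
  expect_equal(dr$ratio, 0.6)
  expect_equal(dr$R_post_star, 1 / 3)
  # limits: post at the sweep minimum, and post equal to pre
  expect_equal(di_response(c(1, 10, 3, 4, 1), 3, R_min = 4)$R_post_star, 0)
  expect_equal(di_response(c(1, 10, 3, 10, 1), 3, R_min = 4)$R_post_star, 1)
  expect_warning(di_response(c(1, 4, 3, 6, 1), 3, R_min = 4), "undefined")
  expect_error(di_response(c(1, 2), di_breaths = integer(0)), "no DI")
})

test_that("normalized interval rescales by the speed-index ratio", {
  expect_equal(normalized_interval(400, 0.05), 400)
  expect_equal(normalized_interval(200, 0.1), 400)
  expect_equal(normalized_interval(200, 0.1, S_c_ref = 0.1), 200)
})

test_that("resistance series starts at the fully dilated reference", {
  cfg <- quick_config(G = 4, n_breaths = 8, T_r = 1)
  traj <- run_simulation(cfg)
  rs <- resistance_series(traj)
  expect_equal(rs$R[1], rs$R0, tolerance = 1e-12)  # breath 1 at full dilation
  expect_true(all(rs$R >= rs$R0 - 1e-9))           # constriction only adds
})
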