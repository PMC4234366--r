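test_that("Poiseuille resistance: r^4 law, linear in length, SI oracle", {
  expect_equal(airway_resistance(0.2, 1) / airway_resistance(0.4, 1), 16)
  expect_equal(airway_resistance(0.3, 0.5), airway_resistance(0.3, 1) / 2)
  # independent unit-analysis oracle: compute in SI and convert
  r_m <- 0.25 / 100; L_m <- 1 / 100; mu <- 1.81e-5
  R_SI <- 8 * mu * L_m / (pi * r_m^4)        # Pa s / m^3
  R_cmH2O_mL <- R_SI * 1e-6 / 98.0665
  expect_equal(airway_resistance(0.25, 1, mu), R_cmH2O_mL, tolerance = 1e-12)
  # closed-airway sentinel
  expect_identical(airway_resistance(c(0, -1), c(1, 1)), c(1e9, 1e9))
})

test_that("uniform symmetric tree splits the tidal volume exactly", {
  for (G in c(0L, 3L, 5L)) {
    tr <- build_tree(G)
    br <- simulate_breath(tr, tr$airways$r0, breath_spec(tidal_volume = 480),
                          terminal_units(tr))
    expect_equal(br$ventilation, rep(480 / 2^G, 2^G), tolerance = 1e-9)
    expect_equal(br$total_inspired, 480)
  }
})

test_that("volume is conserved each breath to 1e-6 relative", {
  tr <- perturb_wall_thickness(build_tree(6), 0.01, 1)
  radii <- tr$airways$r0 * runif(tr$n_airways, 0.3, 1)
  br <- simulate_breath(tr, radii, breath_spec(), terminal_units(tr))
  expect_equal(sum(br$ventilation) / br$total_inspired, 1, tolerance = 1e-6)
})

test_that("a capped airway starves its unit", {
  tr <- build_tree(4)
  radii <- tr$airways$r0
  cap_id <- which(tr$airways$terminal_unit == 5L)
  radii[cap_id] <- tr$airways$r0[cap_id] * wall_params()$r_min_rel
  br <- simulate_breath(tr, radii, breath_spec(), terminal_units(tr))
  expect_lt(br$ventilation[5], min(br$ventilation[-5]))
  expect_lt(br$ventilation[5], 0.15 * mean(br$ventilation))
})

test_that("identical subtrees receive identical flows to machine precision", {
  tr <- build_tree(5)
  radii <- tr$airways$r0
  # same per-generation radii in both root subtrees, heterogeneous per depth
  radii <- radii * (0.5 + 0.4 * (tr$airways$generation %% 2))
  br <- simulate_breath(tr, radii, breath_spec(), terminal_units(tr))
  v <- br$ventilation
  expect_equal(v[1:16], v[17:32], tolerance = 1e-13)
  expect_equal(br$ptm_peak[2], br$ptm_peak[3], tolerance = 1e-13)
})

test_that("halving the time step changes ventilation by < 0.5%", {
  tr <- perturb_wall_thickness(build_tree(4), 0.01, 2)
  radii <- tr$airways$r0 * runif(tr$n_airways, 0.15, 1)
  b1 <- simulate_breath(tr, radii, breath_spec(dt = 0.010), terminal_units(tr))
  b2 <- simulate_breath(tr, radii, breath_spec(dt = 0.005), terminal_units(tr))
  rel <- abs(b1$ventilation - b2$ventilation) /
    pmax(abs(b2$ventilation), mean(b2$ventilation))
  expect_lt(max(rel), 0.005)
})

test_that("peak transmural pressure rises with tidal volume", {
  tr <- build_tree(6)
  radii <- tr$airways$r0 * 0.8
  b1 <- simulate_breath(tr, radii, breath_spec(tidal_volume = 400),
                        terminal_units(tr))
  b2 <- simulate_breath(tr, radii, breath_spec(tidal_volume = 500),
                        terminal_units(tr))
  expect_true(all(b2$ptm_peak > b1$ptm_peak))
})

test_that("tethering vanishes on a homogeneous tree and is off at tau = 0", {
  tr <- build_tree(4)
  u <- terminal_units(tr)
  b_tau <- simulate_breath(tr, tr$airways$r0, breath_spec(), u, wall_params())
  b_no <- simulate_breath(tr, tr$airways$r0, breath_spec(), u,
                          wall_params(tau = 1e-12))
  # homogeneous expansion: the distortion term contributes nothing
  expect_equal(b_tau$ptm_peak, b_no$ptm_peak, tolerance = 1e-9)

  # a starved subtree loses traction only through the tethering term
  radii <- tr$airways$r0
  radii[2] <- radii[2] * 0.02          # constrict one child of the trachea
  h_tau <- simulate_breath(tr, radii, breath_spec(), u, wall_params())
  h_no <- simulate_breath(tr, radii, breath_spec(), u, wall_params(tau = 1e-12))
  expect_lt(h_tau$ptm_peak[2], h_no$ptm_peak[2])
  # and the over-expanding sibling subtree gains traction
  expect_gt(h_tau$ptm_peak[3], h_no$ptm_peak[3])
})

test_that("transmural-pressure traces: peak matches, tau = 0 strips tethering", {
  tr <- build_tree(4)
  radii <- tr$airways$r0
  radii[2] <- radii[2] * 0.05
  br <- simulate_breath(tr, radii, breath_spec(), terminal_units(tr),
                        wall_params(), trace_airways = c(1L, 2L, 3L))
  expect_equal(dim(br$ptm_trace), c(500L, 3L))
  expect_equal(apply(br$ptm_trace, 2, max), br$ptm_peak[1:3])
  # with tau ~ 0 the trace is luminal pressure plus recoil only: siblings
  # with different ventilation still differ through luminal pressure, but
  # the starved subtree is no longer penalized below its tau > 0 trace
  b0 <- simulate_breath(tr, radii, breath_spec(), terminal_units(tr),
                        wall_params(tau = 1e-12), trace_airways = 2L)
  insp <- 1:250    # during expiration a trapped subtree can sit above the
                   # emptying mean, flipping the tether sign
  expect_true(all(br$ptm_trace[insp, 2] <= b0$ptm_trace[insp, 1] + 1e-9))
})

test_that("expiration clamps the airway opening to PEEP", {
  tr <- build_tree(3)
  br <- simulate_breath(tr, tr$airways$r0, breath_spec(peep = 5),
                        terminal_units(tr))
  n <- length(br$inlet_pressure)
  expect_equal(br$inlet_pressure[(n / 2 + 1):n], rep(5, n / 2))
  expect_gt(br$inlet_pressure[n / 2], 5)   # end-inspiration above PEEP
})

test_that("breath spec validates its timing invariants", {
  expect_error(breath_spec(duration = 5, dt = 0.003), "integer number")
  expect_error(breath_spec(tidal_volume = -1))
  expect_error(simulate_breath(build_tree(2), rep(-0.1, 7)))
})
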