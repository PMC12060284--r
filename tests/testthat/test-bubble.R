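test_that("gas density approaches the ideal gas at low pressure and uses the vapor root", {
  rho_ideal <- 101325 * 16.043e-3 / (8.314462618 * 293.15)
  expect_equal(gas_density(c(CH4 = 1), 20, 101325), rho_ideal, tolerance = 0.02)
  # near-ideal doubling at low pressure
  r1 <- gas_density(c(CH4 = 1), 20, 5e4)
  r2 <- gas_density(c(CH4 = 1), 20, 1e5)
  expect_equal(r2 / r1, 2, tolerance = 0.05)
  # the volume translation changes the density at 65 m conditions
  P65 <- pressure_at_depth(65)
  expect_false(isTRUE(all.equal(gas_density(c(CH4 = 1), 7, P65),
                                gas_density(c(CH4 = 1), 7, P65, FALSE))))
  # mixtures accepted, unnamed or unknown components rejected
  expect_gt(gas_density(c(CH4 = 0.5, N2 = 0.3, O2 = 0.2), 7, P65), 0)
  expect_error(gas_density(c(1, 1, 1), 7, P65), "named")
  expect_error(gas_density(c(CH4 = 1), 7, -5), "unphysical")
})

test_that("shape regime follows the Eotvos/Morton diagram", {
  fp <- fluid_properties(7, 34, rho_gas = 5)
  expect_identical(shape_regime(1e-4, fp), "spherical")
  expect_identical(shape_regime(4.5e-3, fp), "ellipsoidal")
  expect_identical(shape_regime(30e-3, fp), "spherical-cap")
  expect_error(shape_regime(-1e-3, fp), "positive")
})

test_that("clean-bubble rise velocity matches the observed band and analytic limits", {
  fp <- fluid_properties(7, 34, rho_gas = 5)
  u45 <- rise_velocity(4.5e-3, fp)
  expect_gte(u45, 0.25)
  expect_lte(u45, 0.35)
  # Stokes/Hadamard-Rybczynski limit for vanishing diameter
  d <- 2e-5
  u_hr <- 9.81 * fp$drho * d^2 / (12 * fp$mu)
  expect_equal(rise_velocity(d, fp), u_hr, tolerance = 0.02)
  # the coded clean correlation peaks near 2 mm and stays within a
  # physically sane band over 1-8 mm
  dd <- seq(1e-3, 8e-3, by = 5e-5)
  uu <- vapply(dd, rise_velocity, numeric(1), fp = fp)
  expect_true(all(uu > 0.15 & uu < 0.36))
  # continuity across the regime boundaries: the blend edges (H = 1.5, 2.5)
  # and the cap threshold (Eo = 40) admit no jump beyond 5%
  boundary_d <- vapply(c(1.5, 2.5, 40), function(target) {
    f <- if (target == 40) {
      function(d) seepfate:::.bubble_numbers(d, fp)$Eo - target
    } else {
      function(d) seepfate:::.bubble_numbers(d, fp)$H - target
    }
    uniroot(f, c(1e-5, 0.05))$root
  }, numeric(1))
  for (db in boundary_d) {
    lo <- rise_velocity(db - 1e-7, fp)
    hi <- rise_velocity(db + 1e-7, fp)
    expect_lt(abs(hi - lo) / lo, 0.05)
  }
  # caps rise faster with size
  big <- vapply(c(20e-3, 30e-3, 40e-3), rise_velocity, numeric(1), fp = fp)
  expect_true(all(diff(big) > 0))
})

test_that("mass transfer coefficient scales with diffusivity and vanishes degenerately", {
  k1 <- mass_transfer_coeff(4.5e-3, "ellipsoidal", 0.28, 1.1e-9)
  k2 <- mass_transfer_coeff(4.5e-3, "ellipsoidal", 0.28, 2.2e-9)
  expect_gt(k2, k1)
  # order 1e-4 m/s within a factor of 3
  expect_true(k1 > 1e-4 / 3 && k1 < 3e-4 * 3)
  expect_identical(mass_transfer_coeff(4.5e-3, "ellipsoidal", 0, 0), 0)
})

test_that("a 4.5 mm bubble from 65 m dissolves almost completely before surfacing", {
  run <- bubble65()
  dep <- run$deposition
  surfaced <- attr(dep, "surfaced")
  expect_gte(sum(dep$fraction), 0.99)
  expect_lte(surfaced, 0.012)
  # conservation: cells + surfaced = 1
  expect_lt(abs(sum(dep$fraction) + surfaced - 1), 1e-9)
  # deposition largest near the release depth, decaying upward
  expect_identical(which.max(dep$fraction), nrow(dep))
  upper <- dep$fraction[1:20]
  expect_lt(max(upper), dep$fraction[nrow(dep)] / 10)
  # surfacing bubble is mostly nitrogen and oxygen
  last <- run$trajectory[nrow(run$trajectory), ]
  expect_lt(last$x_CH4, 0.5)
  # rise velocities in the printed band, ellipsoidal all the way
  expect_true(all(run$trajectory$velocity >= 0.25 & run$trajectory$velocity <= 0.35))
  expect_true(all(run$trajectory$regime == "ellipsoidal"))
})

test_that("no gas exchange means the whole bubble surfaces", {
  run0 <- integrate_bubble(30, profile = ncs_profile(30), kL_scale = 0,
                           dt_out = 2)
  expect_equal(attr(run0$deposition, "surfaced"), 1, tolerance = 1e-9)
  expect_true(all(run0$deposition$fraction == 0))
})

test_that("a shallower release cannot surface less methane", {
  run20 <- fixture("bubble20", function()
    integrate_bubble(20, profile = ncs_profile(20)))
  s65 <- attr(bubble65()$deposition, "surfaced")
  s20 <- attr(run20$deposition, "surfaced")
  expect_gte(s20, s65)
})

test_that("deposition round-trips through CSV", {
  dep <- bubble65()$deposition
  f <- tempfile(fileext = ".csv")
  write_deposition_csv(dep, f)
  back <- read_deposition_csv(f)
  expect_equal(back$fraction, dep$fraction, tolerance = 1e-12)
  expect_equal(attr(back, "surfaced"), attr(dep, "surfaced"), tolerance = 1e-12)
  unlink(f)
})
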