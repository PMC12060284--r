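test_that("wind parametrization of the piston velocity is quadratic through the origin", {
  expect_identical(kw_from_wind(0), 0)
  u <- c(3, 7.5, 12)
  expect_equal(kw_from_wind(2 * u) / kw_from_wind(u), rep(4, 3), tolerance = 1e-14)
  # direct arithmetic oracle at the stated constants
  expect_equal(kw_from_wind(10), 6.97e-7 * 100 * sqrt(660 / 677), tolerance = 1e-12)
  expect_error(kw_from_wind(-1), "non-negative")
})

test_that("a closed column conserves mass to round-off over thousands of steps", {
  set.seed(1)
  C0 <- runif(65, 0.1, 2)
  K <- exp(seq(log(1e-4), log(0.1), length.out = 65))
  r <- cn_step(C0, K, dz = 1, dt = 0.01, k1 = 0, kw = 0, n_steps = 5000)
  expect_lt(abs(r$mass - sum(C0)) / sum(C0), 1e-10)
  expect_equal(r$biodegraded, 0)
  expect_equal(r$ventilated, 0)
})

test_that("pure decay follows the analytic exponential", {
  C0 <- rep(1, 10)
  t12 <- 5
  k1 <- log(2) / t12
  dt <- t12 / 100
  r <- cn_step(C0, 0, dz = 1, dt = dt, k1 = k1, kw = 0, n_steps = 100)
  # Crank-Nicolson rational approximation of exp over 100 steps
  expect_equal(r$mass / sum(C0), exp(-k1 * t12), tolerance = 1e-5)
  expect_equal(r$mass + r$biodegraded, sum(C0), tolerance = 1e-12)
})

test_that("surface exchange drains the top cell first and books the flux", {
  # single step on a 3-cell grid, no diffusion, hand-computable
  C0 <- c(1, 1, 1)
  kw <- 1e-5 * 86400  # m/day
  dt <- 0.01
  r <- cn_step(C0, 0, dz = 1, dt = dt, k1 = 0, kw = 1e-5, n_steps = 1)
  # implicit-average surface sink: C0+ = C0 * (1 - th*a)/(1 + th*a) form
  a <- kw * dt
  c0_new <- (1 - 0.5 * a) / (1 + 0.5 * a)
  expect_equal(r$C[1], c0_new, tolerance = 1e-12)
  expect_equal(r$C[2:3], c(1, 1), tolerance = 1e-15)
  expect_equal(r$ventilated, kw * dt * (0.5 * c0_new + 0.5), tolerance = 1e-12)
  expect_equal(r$mass + r$ventilated, 3, tolerance = 1e-12)
})

test_that("the scheme is second order in space and time, and detects first order", {
  sp <- convergence_order("space")
  expect_equal(sp$order, 2, tolerance = 0.05)
  tm <- convergence_order("time")
  expect_equal(tm$order, 2, tolerance = 0.05)
  be <- convergence_order("time", theta = 1)  # backward Euler harness check
  expect_equal(be$order, 1, tolerance = 0.1)
  expect_true(all(diff(sp$errors) < 0))
})

test_that("depletion runs close the four-component budget everywhere", {
  dep <- bubble65()$deposition
  scen <- scen65()
  for (start in c(0, 182)) {
    bal <- run_until_depleted(dep, scen, t12 = 50, start_day = start)
    resid <- abs(bal$dissolved + bal$biodegraded + bal$ventilated + bal$bubble - 1)
    expect_lt(max(resid), 1e-9)
    expect_true(all(diff(bal$biodegraded) >= 0))
    expect_true(all(diff(bal$ventilated) >= 0))
    expect_true(all(bal$dissolved >= 0))
    expect_true(attr(bal, "terminated"))
    expect_true(all(attr(bal, "final_C") >= 0))
  }
})

test_that("winter starts ventilate, summer starts biodegrade", {
  dep <- bubble65()$deposition
  scen <- scen65()
  jan <- terminal_fractions(run_until_depleted(dep, scen, t12 = 50, start_day = 0))
  jul <- terminal_fractions(run_until_depleted(dep, scen, t12 = 50, start_day = 182))
  expect_gt(jan[["ventilated"]], jan[["biodegraded"]])
  expect_gt(jul[["biodegraded"]], jan[["biodegraded"]])
})

test_that("a closed surface sends everything to biodegradation", {
  dep <- bubble65()$deposition
  scen <- scen65()
  scen$U10[] <- 0  # kw = 0 everywhere
  bal <- run_until_depleted(dep, scen, t12 = 20, start_day = 0)
  fr <- terminal_fractions(bal)
  expect_equal(fr[["ventilated"]], 0, tolerance = 1e-12)
  expect_equal(fr[["biodegraded"]] + fr[["bubble"]], 1, tolerance = 1e-9)
})
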