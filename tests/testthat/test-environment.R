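test_that("seasonal diffusivity is winter-mixed, summer-stratified, and bounded", {
  depth <- seq(0.5, 64.5, by = 1)
  time <- 0:364
  K <- make_seasonal_diffusivity(depth, time, scenario_config())
  expect_true(all(K >= 0))
  expect_true(all(K <= 0.2))
  # January: uniform within 10%
  jan <- K[, 15]
  expect_lt(diff(range(jan)) / mean(jan), 0.1)
  # July: minimum strictly between surface and bottom
  jul <- K[, 196]
  imin <- which.min(jul)
  expect_gt(imin, 1)
  expect_lt(imin, length(depth))
  expect_lt(min(jul), 1e-4)
  # configurable ceiling
  K2 <- make_seasonal_diffusivity(depth, time, scenario_config(k_mixed = 0.5,
                                                               k_ceiling = 0.2))
  expect_lte(max(K2), 0.2)
  expect_error(make_seasonal_diffusivity(rev(depth), time, scenario_config()),
               "increasing")
  expect_error(scenario_config(k_mixed = -1), "negative")
})

test_that("wind series is reproducible, calibrated and clips degenerately", {
  time <- 0:364
  cfg <- scenario_config(wind_mean = 8, wind_sd = 3, wind_ar1 = 0.7)
  u1 <- make_wind_series(time, seed = 4, config = cfg)
  u2 <- make_wind_series(time, seed = 4, config = cfg)
  expect_identical(u1, u2)
  expect_true(all(u1 >= 0))
  # sample mean within 3 AR(1)-adjusted standard errors of the mean
  se <- 3 / sqrt(365) * sqrt((1 + 0.7) / (1 - 0.7))
  expect_lt(abs(mean(u1) - 8), 3 * se)
  u0 <- make_wind_series(time, seed = 1, config = scenario_config(wind_sd = 0))
  expect_identical(u0, rep(8, 365))
  expect_error(make_wind_series(time, 1, scenario_config(wind_mean = -2)))
})

test_that("scenario fields respect physical ranges and the grid contract", {
  scen <- scen65()
  expect_true(all(scen$K >= 0))
  expect_true(all(scen$T >= -2 & scen$T <= 30))
  expect_true(all(scen$S >= 0 & scen$S <= 40))
  expect_true(all(scen$U10 >= 0))
  expect_true(!is.unsorted(scen$depth, strictly = TRUE))
  # last cell edge equals station depth; uniform cells integrate to it
  expect_equal(scen$depth[length(scen$depth)] + scen$dz / 2, scen$station_depth)
  expect_equal(length(scen$depth) * scen$dz, scen$station_depth)
  # fixed seed gives a bit-identical scenario
  expect_identical(make_scenario(65, seed = 7), scen)
  # summer surface is warmer and fresher than the interior
  prof_jul <- scenario_profile(scen, 196)
  expect_gt(prof_jul$T[1], prof_jul$T[60])
  expect_lt(prof_jul$S[1], prof_jul$S[60])
})

test_that("scenario round-trips through plain-text files", {
  scen <- scen65()
  d <- tempfile("scen")
  write_scenario(scen, d)
  back <- read_scenario(d)
  expect_equal(back$K, scen$K, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$T, scen$T, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$U10, scen$U10, tolerance = 1e-12)
  expect_equal(back$station_depth, scen$station_depth)
  expect_equal(unclass(back$config), unclass(scen$config))
  unlink(d, recursive = TRUE)
})

test_that("simulated tracer data follow the generating model exactly at zero noise", {
  des0 <- tracer_design(noise_scale = 0)
  d0 <- simulate_tracer_experiment(des0, seed = 1)
  p <- des0$true_params
  # controls sit at Cb, pre-incubation samples at Ctot
  expect_true(all(d0$activity_normalized[d0$kind == "control"] == p$Cb))
  expect_true(all(d0$activity_normalized[d0$kind == "pre"] == p$Ctot))
  # all points on the curve to 1e-12 of Ctot
  mu <- seepfate:::.model_mean(p, d0)
  expect_lt(max(abs(d0$activity_normalized - mu)), 1e-12 * p$Ctot)
  # warm flasks approach Ctot faster at equal days
  for (day in c(2, 4, 13)) {
    a5 <- mu[d0$kind == "test" & d0$day == day & d0$temperature_C == 5][1]
    a85 <- mu[d0$kind == "test" & d0$day == day & d0$temperature_C == 8.5][1]
    expect_gt(a85, a5)
  }
  # determinism and noise reproducibility
  d1 <- simulate_tracer_experiment(tracer_design(), seed = 9)
  d2 <- simulate_tracer_experiment(tracer_design(), seed = 9)
  expect_identical(d1, d2)
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write_tracer_csv(d1, f)
  expect_equal(read_tracer_csv(f)$activity_normalized, d1$activity_normalized,
               tolerance = 1e-12)
  unlink(f)
})
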