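test_that("box-model branching has the closed-form limits", {
  expect_equal(box_model_fraction(1, 30, 0), 1)
  expect_equal(box_model_fraction(0, 30, 0.1), 0)
  expect_equal(box_model_fraction(3, 30, 0.1), 0.5)  # kw/H = k1
  expect_error(box_model_fraction(0, 30, 0), "zero")
})

test_that("ventilation rate is zero without surface exchange and ~kw/H when mixed", {
  dep <- dep_uniform30()
  scen <- scen_mixed()
  bal <- run_until_depleted(dep, scen, t12 = 30, start_day = 0, out_every = 20)
  v <- ventilation_rate(bal)
  kwH <- kw_from_wind(8) * 86400 / 30
  mid <- v$v[!is.na(v$v)][5:40]
  expect_equal(mean(mid), kwH, tolerance = 0.02)
  scen0 <- scen_mixed()
  scen0$U10[] <- 0
  bal0 <- run_until_depleted(dep, scen0, t12 = 30, start_day = 0)
  v0 <- ventilation_rate(bal0)
  expect_true(all(v0$v[!is.na(v0$v)] == 0))
})

test_that("stratification suppresses the ventilation rate at equal wind", {
  dep <- bubble65()$deposition
  scen <- scen65()
  scen$U10[] <- 8
  vjan <- ventilation_rate(run_until_depleted(dep, scen, t12 = 50, start_day = 0,
                                              out_every = 50))
  vjul <- ventilation_rate(run_until_depleted(dep, scen, t12 = 50, start_day = 182,
                                              out_every = 50))
  early <- function(v) mean(v$v[v$time <= 30], na.rm = TRUE)
  expect_gt(early(vjan), early(vjul))
})

test_that("annual ensemble hits the no-decay and instant-decay limits", {
  dep <- bubble65()$deposition
  scen <- scen65()
  slow <- annual_ensemble(dep, scen, t12 = 5e4, n_starts = 4, max_days = 40000)
  expect_lt(slow$mean[["biodegraded"]], 0.05)
  expect_equal(slow$mean[["ventilated"]] + slow$mean[["bubble"]], 1,
               tolerance = 0.05)
  fast <- annual_ensemble(dep, scen, t12 = 1e-2, n_starts = 4)
  expect_gt(fast$mean[["biodegraded"]], 0.999 * (1 - fast$mean[["bubble"]]))
  # mean lies within the member envelope
  ens <- annual_ensemble(dep, scen, t12 = 30, n_starts = 6)
  for (col in c("bubble", "ventilated", "biodegraded")) {
    expect_gte(ens$mean[[col]], min(ens$members[[col]]) - 1e-12)
    expect_lte(ens$mean[[col]], max(ens$members[[col]]) + 1e-12)
  }
  # member fractions are exact partitions
  sums <- rowSums(ens$members[, c("bubble", "ventilated", "biodegraded")])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("ensemble matches the box-model oracle on a permanently mixed column", {
  dep <- dep_uniform30()
  scen <- scen_mixed()
  kw_day <- kw_from_wind(8) * 86400
  for (t12 in c(3, 10, 30, 100, 300)) {
    ens <- annual_ensemble(dep, scen, t12 = t12, n_starts = 4)
    oracle <- box_model_fraction(kw_day, 30, log(2) / t12)
    expect_equal(ens$mean[["ventilated"]], oracle, tolerance = 0.01)
  }
})

test_that("half-life sweep: biodegradation decreases, bubble share constant", {
  dep <- bubble65()$deposition
  scen <- scen65()
  grid <- c(2, 10, 50, 250, 1000)
  fs <- halflife_sweep(dep, scen, halflife_days = grid, n_starts = 4)
  expect_true(all(diff(fs$frac_biodegraded) < 0))
  expect_true(all(abs(fs$frac_bubble - fs$frac_bubble[1]) < 1e-12))
  sums <- fs$frac_bubble + fs$frac_ventilated + fs$frac_biodegraded
  expect_true(all(abs(sums - 1) < 1e-9))
  # a one-point sweep equals a direct ensemble call
  ens <- annual_ensemble(dep, scen, t12 = 50, n_starts = 4)
  one <- halflife_sweep(dep, scen, halflife_days = 50, n_starts = 4)
  expect_equal(one$frac_biodegraded, ens$mean[["biodegraded"]], tolerance = 1e-12)
})
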