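test_that("native drive is a wi-scaled spaced sawtooth", {
  phases <- seq(0, 0.999, by = 0.001)
  d <- native_drive(phases, wi = 1, insp_frac = 0.4)
  expect_equal(native_drive(phases, wi = 0), rep(0, length(phases)))
  expect_equal(max(d), 1, tolerance = 3e-3)         # peak at ramp end
  expect_true(all(d[phases >= 0.4] == 0))           # spaced fraction silent
  ramp <- d[phases < 0.4]
  expect_true(all(diff(ramp) > 0))                  # linear rise
  # linear attenuation: wi = 0.75 is the intact waveform scaled pointwise
  expect_equal(native_drive(phases, wi = 0.75), 0.75 * d)
})

test_that("activation combines linearly and clips at 1", {
  expect_equal(combine_activation(0.4, 0), 0.4)
  expect_equal(combine_activation(0.9, 0.3), 1)
  expect_equal(combine_activation(0, 0.35), 0.35)
  expect_equal(combine_activation(c(0.2, 0.8), c(0.3, 0.5)), c(0.5, 1))
})

test_that("lung at rest stays at rest; released spring does not ring", {
  p <- plant_params()
  st <- plant_init_state(p)
  for (i in 1:200) st <- lung_step(st, p, 0)
  expect_equal(st$volume, 0)
  expect_equal(st$xd, 0)

  # step activation, then release: the damped spring returns to baseline
  # without sustained oscillation (at most one overshoot)
  for (i in 1:2000) st <- lung_step(st, p, 0.8)
  expect_gt(st$volume, 0.5)
  xs <- numeric(2000)
  for (i in 1:2000) { st <- lung_step(st, p, 0); xs[i] <- st$x }
  crossings <- sum(diff(sign(xs[abs(xs) > 1e-9])) != 0)
  expect_lte(crossings, 1)
  expect_lt(abs(xs[2000]), 1e-6)

  st$x <- NaN
  expect_error(lung_step(st, p, 0), "non-finite")
})

test_that("CO2 bookkeeping balances exactly and never goes negative", {
  p <- plant_params()
  run <- run_plant(p, wi = 1, mbc = 1, duration_s = 8, dynamic_rr = FALSE)
  st <- run$state
  expect_equal(st$co2, p$co2_base + st$co2_produced - st$co2_cleared,
               tolerance = 1e-9)
  expect_true(all(run$co2 >= 0))

  # zero ventilation: growth is exactly linear at rate mbc*mbc0
  st0 <- plant_init_state(p)
  st0$exhaled_mL <- 0
  for (i in 1:1000) st0 <- metabolism_step(st0, p, 1.3)
  expect_equal(st0$co2, p$co2_base + 1.3 * p$mbc0 * 1000 * p$dt)
})

test_that("excess demand at fixed eupneic breathing accumulates CO2", {
  p <- calibrated_plant()
  q <- p; q$rr_reg <- c(p$rr0, 0)   # hold the rate at eupnea regardless of mbc
  base <- run_plant(q, wi = 1, mbc = 1, duration_s = 30, dynamic_rr = FALSE)
  high <- run_plant(q, wi = 1, mbc = 1.11, duration_s = 30, dynamic_rr = FALSE)
  # steady breath-boundary CO2 at baseline demand is flat within 0.5%
  b <- base$co2[seq(40000, 60000, by = 2143)]
  expect_lt(max(abs(diff(b))) / p$co2_base, 0.005)
  # +11% production with rate and depth held: CO2 accumulates breath over
  # breath (7.5 s windows hold exactly 7 breaths at 56/min, so the window
  # means are free of intra-breath phase)
  win <- function(run) vapply(0:3, function(k) {
    mean(run$co2[(k * 15000 + 1):((k + 1) * 15000)])
  }, numeric(1))
  hb <- win(base); hh <- win(high)
  expect_true(all(diff(hh[2:4]) > 0 | hh[2:4][-1] > 1.05))
  expect_gt(hh[4], hb[4] * 1.05)   # settles toward the +11% level
})

test_that("RR regression: feed-forward values and positive slope", {
  p <- calibrated_plant()
  expect_error(dynamical_rr(1, NULL), "not fitted")
  expect_error(dynamical_rr(1, c(NA, 56)), "not fitted")
  expect_gt(p$rr_reg[2], 0)
  expect_equal(dynamical_rr(1, p$rr_reg), 56, tolerance = 0.02)
  expect_gt(dynamical_rr(1.11, p$rr_reg), dynamical_rr(1, p$rr_reg))
})

test_that("calibrated eupnea holds the reference rate and depth", {
  rec <- eupnea_run()$records
  expect_equal(tail_mean(rec$rr), 56, tolerance = 0.02)
  expect_equal(tail_mean(rec$vt), 2, tolerance = 0.02)
  # minute ventilation identity: metrics product vs integrated inspired
  # volume per minute
  run <- eupnea_run()
  p <- calibrated_plant()
  insp <- sum(pmax(diff(run$volume[run$time_s > 30]), 0)) / 30 * 60
  expect_equal(tail_mean(rec$minute_ventilation), insp, tolerance = 0.02)
})

test_that("calibration is idempotent", {
  p <- calibrated_plant()
  p2 <- calibrate_plant(p, fit_regression = FALSE)
  expect_equal(p2$F_max, p$F_max, tolerance = 0.005)
  expect_equal(p2$k_ex, p$k_ex, tolerance = 0.01)
})

test_that("injury lowers depth and raises the settled rate, in order", {
  p <- calibrated_plant()
  rr_ref <- tail_mean(eupnea_run()$records$rr)
  norm <- vapply(c(0.9, 0.8, 0.75), function(wi) {
    run <- run_plant(p, wi = wi, mbc = 1, duration_s = 60)
    expect_lt(tail_mean(run$records$vt), 2)
    tail_mean(run$records$rr) / rr_ref
  }, numeric(1))
  expect_true(all(diff(norm) > 0))   # severity increases the settled rate
  expect_true(all(norm > 1))
})

test_that("higher metabolic demand raises the settled rate toward the regression", {
  p <- calibrated_plant()
  r11 <- run_plant(p, wi = 1, mbc = 1.11, duration_s = 60)
  expect_gt(tail_mean(r11$records$rr), 56)
  expect_equal(tail_mean(r11$records$rr), dynamical_rr(1.11, p$rr_reg),
               tolerance = 0.02)
})
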