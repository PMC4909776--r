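test_that("controller-off scenario reproduces the bare plant step for step", {
  p <- calibrated_plant()
  sc <- scenario("off", wi = 0.85, controller_mode = "off", duration_s = 8)
  r1 <- run_scenario(sc, p)
  r2 <- run_plant(p, wi = 0.85, mbc = 1, duration_s = 8)
  expect_identical(r1$volume, r2$volume)
  expect_identical(r1$co2, r2$co2)
  expect_equal(length(r1$volume), round(8 / p$dt))   # loop timing
})

test_that("off equals closed loop with stimulation forced to zero", {
  p <- calibrated_plant()
  cfg <- reference_config("closed_loop")
  sc_on <- scenario("forced", wi = 0.9, controller_mode = "closed_loop",
                    duration_s = 6)
  sc_off <- scenario("off", wi = 0.9, controller_mode = "off", duration_s = 6)
  rz <- run_scenario(sc_on, p, cfg, force_zero_stim = TRUE)
  ro <- run_scenario(sc_off, p)
  expect_identical(rz$volume, ro$volume)
  expect_identical(rz$co2, ro$co2)
})

test_that("scenarios are deterministic and validated", {
  p <- calibrated_plant()
  cfg <- reference_config("open_loop")
  sc <- scenario("det", wi = 0, controller_mode = "open_loop", duration_s = 5,
                 seed = 7)
  r1 <- run_scenario(sc, p, cfg)
  r2 <- run_scenario(sc, p, cfg)
  expect_identical(r1$volume, r2$volume)
  expect_identical(r1$stim, r2$stim)

  expect_error(scenario("bad", mbc_schedule = data.frame(t_s = c(10, 0),
                                                         multiplier = c(1, 2))))
  p2 <- p; p2$dt <- 1e-3
  expect_error(run_scenario(sc, p2, cfg), "dt differ")
  cfg_nf <- reference_config("open_loop", include_follower = FALSE)
  expect_error(run_scenario(sc, p, cfg_nf), "I_inc")
  expect_error(run_scenario(sc, p, cfg, p_inj = c(1, 2, 3)), "P_inj")
})

test_that("metabolic demand schedule is applied from its switch time", {
  p <- calibrated_plant()
  sc <- scenario("sched", wi = 1,
                 mbc_schedule = data.frame(t_s = c(0, 5), multiplier = c(1, 1.5)),
                 controller_mode = "off", duration_s = 10)
  run <- run_scenario(sc, p)
  produced <- run$plant_state$co2_produced
  expect_equal(produced, p$mbc0 * (5 * 1 + 5 * 1.5), tolerance = 1e-3)
})

test_that("the six reference injury/demand pairs are enumerated", {
  pairs <- reference_pairs()
  expect_equal(nrow(pairs), 6)
  expect_setequal(unique(pairs$wi), c(0.9, 0.8, 0.75))
  expect_setequal(unique(pairs$mbc), c(1.11, 1.17))
  for (i in seq_len(6)) {
    pi <- reference_p_inj(pairs$wi[i], pairs$mbc[i])
    expect_equal(length(pi), 2)
  }
})

test_that("complete-injury open loop sustains a stimulated rhythm", {
  p <- calibrated_plant()
  cfg <- reference_config("open_loop")
  sc <- scenario("ol", wi = 0, controller_mode = "open_loop", duration_s = 15)
  run <- run_scenario(sc, p, cfg)
  rec <- run$records
  expect_gt(nrow(rec), 10)
  expect_gt(tail_mean(rec$vt, 5), 0.5)      # real volume excursions
  expect_gt(max(run$stim), 0.3)             # driven by the follower burst
  expect_equal(run$native, rep(0, length(run$native)))  # no native drive
})

test_that("fixtures are reproducible and noise-tolerant", {
  p <- calibrated_plant()
  f1 <- generate_fixtures(p, seed = 5, duration_s = 12)
  f2 <- generate_fixtures(p, seed = 5, duration_s = 12)
  expect_identical(f1$volume_noisy, f2$volume_noisy)
  rec <- segment_breaths(f1$volume, p$dt)
  expect_equal(tail_mean(rec$rr, 5), 56, tolerance = 0.02)
  recn <- segment_breaths(f1$volume_noisy, p$dt)
  expect_equal(nrow(recn), nrow(rec))
  expect_equal(dim(f1$raster), c(20, 5))
})

test_that("trace and summary files round-trip", {
  p <- calibrated_plant()
  sc <- scenario("io", wi = 1, controller_mode = "off", duration_s = 12)
  run <- run_scenario(sc, p)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_trace_csv(run, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), length(run$volume) / 2)  # 1 ms downsampling
  expect_named(df, c("time_s", "volume_mL", "co2", "native", "stim", "activation"))
  write_summary_json(run, js)
  s <- jsonlite::read_json(js)
  expect_equal(s$scenario, "io")
  expect_equal(s$rr, run$summary$rr, tolerance = 1e-8)
  unlink(c(csv, js))
})

test_that("theta calibration selects a stable rhythm on a coarse grid", {
  p <- calibrated_plant()
  cal <- calibrate_theta(p, thetas = c(100, 120), duration_s = 15)
  expect_true(cal$theta %in% c(100, 120))
  expect_true(all(is.finite(cal$table$rr)))
  expect_error(calibrate_theta(p, thetas = 5000, duration_s = 5),
               "no stable rhythm")
})
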