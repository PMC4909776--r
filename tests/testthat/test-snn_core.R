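# The kinetic table values asserted here are the reference parameterization
# of the five synapse kinetics (rise constants A, decay constants C, steady
# states r_inf), derived from the binding rates at the 0.5 ms step.

test_that("kinetic constants reproduce the reference table", {
  tab <- kinetic_table()
  expect_equal(tab$A, c(0.0290, 0.0575, 0.1150, 0.2250, 0.4500), tolerance = 1e-10)
  expect_equal(tab$B, c(0.9685, 0.9375, 0.8750, 0.7500, 0.5000), tolerance = 1e-10)
  expect_equal(tab$C, c(0.9975, 0.9950, 0.9900, 0.9750, 0.9500), tolerance = 1e-10)
  expect_equal(round(tab$r_inf, 2), c(0.92, 0.92, 0.92, 0.90, 0.90))
  expect_equal(round(tab$tau_r_ms, 1), c(15.9, 8.0, 4.0, 2.0, 1.0))

  k5 <- derive_kinetic_constants(900, 100)
  expect_equal(k5$A, 0.45)
  expect_equal(k5$B, 0.50)
  expect_equal(k5$C, 0.95)
  expect_equal(k5$r_inf, 0.90)
  expect_equal(k5$tau_r_ms, 1.0)

  k0 <- derive_kinetic_constants(0, 40)
  expect_equal(k0$A, 0)
  expect_equal(k0$r_inf, 0)
  expect_equal(k0$C, 1 - 5e-4 * 40)

  expect_error(derive_kinetic_constants(3000, 1000, dt = 5e-4), "unstable")
})

test_that("kinetic step follows the two branches and stays in [0,1]", {
  k5 <- derive_kinetic_constants(900, 100)
  expect_equal(kinetic_step(0, TRUE, k5), 0.45)
  expect_equal(kinetic_step(0, FALSE, k5), 0)

  # one rising Euler step of dr/dt = alpha(1-r) - beta r equals B*r + A
  r0 <- 0.3
  euler <- r0 + 5e-4 * (900 * (1 - r0) - 100 * r0)
  expect_equal(kinetic_step(r0, TRUE, k5), euler)

  # iterated rising branch converges to r_inf = A/(1-B)
  r <- 0
  for (i in 1:20) r <- kinetic_step(r, TRUE, k5)
  expect_lt(abs(r - 0.90), 1e-3)

  # decay branch is geometric with ratio C
  r <- 0.8
  for (i in 1:10) r <- kinetic_step(r, FALSE, k5)
  expect_equal(r, 0.8 * k5$C^10)
})

test_that("r stays bounded under random spike sequences (both backends)", {
  ros <- network_roster("pair", c("a", "b"),
    data.frame(pre = c("a", "a"), post = c("b", "b"), kinetic = c(5L, 1L),
               P = c(1000, -500), plastic_tag = "none"))
  set.seed(42)
  for (backend in c("float", "fixed")) {
    net <- compile_network(ros, lif = lif_params(theta = 50), backend = backend)
    st <- snn_init_state(net)
    for (i in 1:500) {
      st <- network_step(net, st, forced_spikes = c(runif(1) < 0.4, FALSE))
      r <- network_r(net, st)
      expect_true(all(r >= 0 & r <= 1))
    }
  }
})

test_that("TPP is the signed sum of P*r over incoming connections", {
  ros <- network_roster("tpp", c("a", "b", "c"),
    data.frame(pre = c("a", "b", "a"), post = c("c", "c", "b"),
               kinetic = c(4L, 4L, 4L), P = c(400, -500, 1280),
               plastic_tag = "none"))
  net <- compile_network(ros, backend = "float")
  st <- snn_init_state(net)
  expect_equal(total_postsynaptic_potential(net, st, "c"), 0)  # empty r
  st$r <- c(1, 0.8, 0.5)
  expect_equal(total_postsynaptic_potential(net, st, "c"), 400 * 1 - 500 * 0.8)
  expect_equal(total_postsynaptic_potential(net, st, "b"), 1280 * 0.5)
  expect_equal(total_postsynaptic_potential(net, st, "a"), 0)
})

test_that("membrane relaxes toward constant input with ratio 1 - 2^-shift", {
  ros <- network_roster("one", "a",
    data.frame(pre = "a", post = "a", kinetic = 5L, P = 0,
               plastic_tag = "none"))
  net <- compile_network(ros, lif = lif_params(theta = 1e6, leak_shift = 3),
                         backend = "float")
  st <- snn_init_state(net)
  tpp <- 2000
  v_prev <- 0
  for (i in 1:50) {
    st <- network_step(net, st, ext_tpp = tpp)
    expect_equal(st$v, v_prev + (tpp - v_prev) / 8)
    v_prev <- st$v
  }
  # geometric approach to tpp with ratio 7/8
  expect_equal(tpp - st$v, tpp * (7 / 8)^50, tolerance = 1e-9)

  # v = 8 with no input leaks to 7 (one shift step)
  st2 <- snn_init_state(net); st2$v <- 8
  st2 <- network_step(net, st2)
  expect_equal(st2$v, 7)
})

test_that("spike, one-step refractory reset, and spike history", {
  ros <- network_roster("one", "a",
    data.frame(pre = "a", post = "a", kinetic = 5L, P = 0,
               plastic_tag = "none"))
  for (backend in c("float", "fixed")) {
    net <- compile_network(ros, lif = lif_params(theta = 160), backend = backend)
    st <- snn_init_state(net)
    spikes <- integer(40)
    for (i in 1:40) {
      st <- network_step(net, st, ext_tpp = 2000)
      spikes[i] <- st$spike
    }
    # drive 2000 >> theta: spike every other step (refractory in between)
    expect_equal(spikes, rep(c(1L, 0L), 20))
    # no two consecutive spikes ever
    expect_true(all(spikes[-1] + spikes[-40] <= 1))
    # history popcount matches the raster
    expect_equal(st$hist_cnt, sum(spikes[21:40]))
  }
})

test_that("quiescent network stays quiescent and runs are deterministic", {
  ros <- build_open_loop(include_follower = TRUE)
  net <- compile_network(ros, lif = lif_params(theta = 100, pulse_steps = 24))
  tr <- run_network(net, 200)
  expect_true(all(tr$spike == 0))
  expect_true(all(tr$v == 0))
  expect_equal(tr$state$t, 200L)
  expect_equal(length(tr$time_s), 200)
  expect_equal(tr$time_s[200], 0.1)  # 200 steps = 100 ms at 2 kHz

  ext <- numeric(net$n_neurons); ext[match("ON", net$neurons)] <- 200
  t1 <- run_network(net, 1500, ext_tpp_fun = function(s) ext)
  t2 <- run_network(net, 1500, ext_tpp_fun = function(s) ext)
  expect_identical(t1$spike, t2$spike)
  expect_error(run_network(net, 10, probes = "nope"), "unknown probe")
})

test_that("phase discipline: permuting roster order leaves dynamics intact", {
  ros <- build_open_loop(include_follower = TRUE)
  perm <- c(4, 1, 7, 2, 8, 3, 6, 5)
  ros2 <- ros
  ros2$neurons <- ros$neurons[perm]
  net1 <- compile_network(ros, lif = lif_params(theta = 100, pulse_steps = 24))
  net2 <- compile_network(ros2, lif = lif_params(theta = 100, pulse_steps = 24))
  ext1 <- numeric(8); ext1[match("ON", net1$neurons)] <- 200
  ext2 <- numeric(8); ext2[match("ON", net2$neurons)] <- 200
  t1 <- run_network(net1, 2000, ext_tpp_fun = function(s) ext1)
  t2 <- run_network(net2, 2000, ext_tpp_fun = function(s) ext2)
  expect_identical(t1$spike[, net1$neurons], t2$spike[, net1$neurons])
})

test_that("fan-in above the hardware limit is rejected", {
  conn <- data.frame(pre = letters[1:9], post = "z", kinetic = 1L, P = 10,
                     plastic_tag = "none")
  ros <- network_roster("over", c(letters[1:9], "z"), conn)
  expect_error(compile_network(ros), "fan-in limit")
  expect_silent(compile_network(ros, max_fan_in = 9))
})
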