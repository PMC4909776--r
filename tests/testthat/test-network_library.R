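# The printed connection grid and the connectivity-density accounting.
# Printed densities are truncated (not rounded) to one decimal, so the
# comparisons here floor to 1 d.p.

trunc1 <- function(x) floor(x * 10) / 10

test_that("open-loop roster matches the printed grid", {
  ros <- build_open_loop()
  expect_equal(length(ros$neurons), 7)
  expect_equal(nrow(ros$connections), 16)
  expect_equal(ros$external_inputs, 1)

  cn <- ros$connections
  get <- function(pre, post) cn[cn$pre == pre & cn$post == post, ]
  # grid labels are accepted via the aliases
  e1 <- get("IE", "E_dec")  # Edec_TON -> Edec_OUT
  expect_equal(e1$kinetic, 1L); expect_equal(e1$P, 5000)
  expect_equal(e1$plastic_tag, "P_f")
  e2 <- get("E_dec", "IE")
  expect_equal(e2$kinetic, 1L); expect_equal(e2$P, -2200)
  e3 <- get("I_dec", "I_decTON")  # Idec_OUT -> Idec_TON
  expect_equal(e3$kinetic, 3L); expect_equal(e3$P, -5000)
  e4 <- get("ON", "IE")
  expect_equal(e4$kinetic, 4L); expect_equal(e4$P, 1280)
  e5 <- get("EI", "EI_TON")
  expect_equal(e5$kinetic, 2L); expect_equal(e5$P, 1280)
  # mixed excitation and inhibition present
  expect_true(any(cn$P > 0) && any(cn$P < 0))
  expect_equal(sort(unique(sign(cn$P))), c(-1, 1))
})

test_that("alias names resolve to canonical neurons", {
  conn <- data.frame(pre = "Edec_OUT", post = "Edec_TON", kinetic = 1L,
                     P = -2200, plastic_tag = "none")
  ros <- network_roster("alias", c("IE", "E_dec"), conn)
  expect_equal(ros$connections$pre, "E_dec")
  expect_equal(ros$connections$post, "IE")
})

test_that("closed-loop roster adds the three tonic sensor neurons", {
  cl <- build_closed_loop()
  expect_equal(length(cl$neurons), 10)
  expect_equal(nrow(cl$connections), 24)
  expect_equal(cl$external_inputs, 3)
  expect_true(all(c("Vol_spk", "C1_spk", "C2_spk") %in% cl$neurons))
  expect_true("P_inj" %in% cl$connections$plastic_tag)

  # construction inverse: stripping the sensors recovers the open loop
  back <- strip_tonic_sensors(cl)
  ol <- build_open_loop()
  expect_equal(back$neurons, ol$neurons)
  expect_equal(back$connections[order(back$connections$pre, back$connections$post), ],
               ol$connections[order(ol$connections$pre, ol$connections$post), ],
               ignore_attr = TRUE)
})

test_that("connectivity densities reproduce the reference accounting", {
  # open loop: 16 printed pairs + 1 external trigger = 17, 7 neurons, MaxC 3
  st <- connectivity_stats(build_open_loop(), include_external = TRUE)
  expect_equal(st$C, 17)
  expect_equal(st$N, 7)
  expect_equal(st$MaxC, 3)
  expect_equal(trunc1(st$all_to_all), 34.6)
  expect_equal(trunc1(st$maxc_to_all), 80.9)
  expect_equal(trunc1(st$eight_to_all), 30.3)
  expect_equal(trunc1(st$c_per_n), 2.4)

  # closed loop: 24 internal connections, 10 neurons, MaxC 4
  st2 <- connectivity_stats(build_closed_loop())
  expect_equal(st2$C, 24)
  expect_equal(st2$N, 10)
  expect_equal(st2$MaxC, 4)
  expect_equal(st2$all_to_all, 24.0)
  expect_equal(st2$maxc_to_all, 60.0)
  expect_equal(st2$eight_to_all, 30.0)
  expect_equal(trunc1(st2$c_per_n), 2.4)

  # direct-count interface and degenerate cases
  expect_equal(connectivity_stats(C = 0, N = 5, MaxC = 0)$all_to_all, 0)
  expect_error(connectivity_stats(C = 3, N = 0, MaxC = 1), "empty roster")
})

test_that("no reference roster violates the hardware fan-in limit", {
  for (ros in list(build_open_loop(), build_open_loop(include_follower = TRUE),
                   build_closed_loop(),
                   build_closed_loop(build_open_loop(include_follower = TRUE)))) {
    fan_in <- table(ros$connections$post)
    expect_true(all(fan_in <= 8))
    expect_silent(compile_network(ros, lif = lif_params(theta = 100)))
  }
})

test_that("rosters round-trip through the YAML config format", {
  path <- tempfile(fileext = ".yaml")
  ros <- build_closed_loop(build_open_loop(include_follower = TRUE))
  write_roster_yaml(ros, path)
  back <- read_roster_yaml(path)
  expect_equal(back$neurons, ros$neurons)
  expect_equal(back$external_inputs, ros$external_inputs)
  expect_equal(back$connections, ros$connections, ignore_attr = TRUE)
  unlink(path)
})
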