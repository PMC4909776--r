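# Stimulation interface: follower activity to muscle drive, and plant
# sensors to tonic-neuron spike trains.
#
# The muscle drive each step is the stimulation ratio: the follower
# neuron's spike count over the trailing 20 computation steps (10 ms)
# divided by 20, i.e. a fraction of maximum activation with resolution
# 1/20. Sensors are rate-coded by a deterministic clocked divider
# (accumulate frequency*dt, emit a spike on overflow), which keeps runs
# bit-reproducible; a seeded stochastic (Bernoulli) variant is available.

#' Stimulation ratio from a 20-step spike window
#'
#' @param spike_history Integer/logical vector of exactly 20 spike bits.
#' @return Fraction in \[0, 1\]: popcount/20 (0 spikes = 0, 10 = 0.5,
#'   20 = 1).
#' @export
stimulation_ratio <- function(spike_history) {
  if (length(spike_history) != 20) {
    stop("stimulation_ratio: window must be exactly 20 steps, got ",
         length(spike_history))
  }
  sum(spike_history != 0) / 20
}

#' Sensor encoder configuration
#'
#' Piecewise-linear, clamped transfer from a sensor value to an
#' instantaneous spike frequency. These transfer curves and gains are
#' package calibration values (the roles of the tonic neurons are given;
#' their codes are not).
#'
#' @param v_min,v_max Input range mapped to \[0, f_max\].
#' @param f_max Maximum spike frequency, Hz (capped by the refractory-
#'   limited 1000 Hz at the 0.5 ms step).
#' @param mode `"divider"` (deterministic clocked divider) or
#'   `"bernoulli"` (per-step spike probability `freq*dt`, seeded by the
#'   harness).
#' @param dt Step, s.
#' @return List of class `encoder_cfg`.
#' @export
encoder_cfg <- function(v_min = 0, v_max = 2, f_max = 400,
                        mode = c("divider", "bernoulli"), dt = 5e-4) {
  mode <- match.arg(mode)
  stopifnot(v_max > v_min, f_max > 0, f_max <= 1 / (2 * dt) * 2)
  list(v_min = v_min, v_max = v_max, f_max = f_max, mode = mode, dt = dt)
}

encoder_freq <- function(v, cfg) {
  frac <- (v - cfg$v_min) / (cfg$v_max - cfg$v_min)
  cfg$f_max * min(max(frac, 0), 1)
}

#' Initialize encoder state (divider phase)
#'
#' @return Encoder state (accumulator at 0).
#' @export
encoder_init <- function() list(acc = 0)

#' One encoder step: sensor value to spike bit
#'
#' @param state Encoder state from [encoder_init()].
#' @param v Sensor value.
#' @param cfg [encoder_cfg()].
#' @return List `spike` (0/1) and updated `state`.
#' @export
encoder_step <- function(state, v, cfg) {
  f <- encoder_freq(v, cfg)
  if (cfg$mode == "divider") {
    acc <- state$acc + f * cfg$dt
    spike <- if (acc >= 1) 1L else 0L
    if (spike) acc <- acc - 1
    list(spike = spike, state = list(acc = acc))
  } else {
    spike <- as.integer(stats::runif(1) < f * cfg$dt)
    list(spike = spike, state = state)
  }
}

#' Encode a whole series of sensor values (testing helper)
#'
#' @param values Numeric vector of sensor samples, one per step.
#' @param cfg [encoder_cfg()].
#' @return Integer vector of spike bits.
#' @export
encode_series <- function(values, cfg) {
  st <- encoder_init()
  out <- integer(length(values))
  for (i in seq_along(values)) {
    r <- encoder_step(st, values[i], cfg)
    out[i] <- r$spike
    st <- r$state
  }
  out
}

#' Volume encoder: lung volume to Vol_spk spike bit
#'
#' Rate coding: spike frequency rises linearly (clamped) with volume over
#' the calibrated range, 0 at the baseline volume.
#'
#' @param state Encoder state.
#' @param volume Lung volume, mL.
#' @param cfg [encoder_cfg()]; default range 0--2 mL.
#' @return As [encoder_step()].
#' @export
encode_volume <- function(state, volume, cfg = encoder_cfg()) {
  encoder_step(state, volume, cfg)
}

#' CO2 encoders: excess and deficit channels
#'
#' C1_spk fires at a rate increasing with the CO2 excess over baseline,
#' C2_spk with the deficit; both are silent at baseline (dead-band centre).
#'
#' @param state List with `c1` and `c2` encoder states.
#' @param co2 Current CO2 amount.
#' @param baseline Baseline CO2 amount (> 0).
#' @param cfg [encoder_cfg()] for the relative-error input; default maps a
#'   20% excess/deficit to the maximum rate.
#' @return List `c1`, `c2` (spike bits) and updated `state`.
#' @export
encode_co2 <- function(state, co2, baseline,
                       cfg = encoder_cfg(v_min = 0, v_max = 0.2, f_max = 400)) {
  stopifnot(baseline > 0)
  rel <- (co2 - baseline) / baseline
  r1 <- encoder_step(state$c1, max(rel, 0), cfg)
  r2 <- encoder_step(state$c2, max(-rel, 0), cfg)
  list(c1 = r1$spike, c2 = r2$spike,
       state = list(c1 = r1$state, c2 = r2$state))
}
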