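# Experiment harness: reference configurations, the closed loop joining
# controller, stimulation interface and plant at the shared 0.5 ms step,
# the bit-width accuracy sweep, and fixture generation.

#' Reference controller configuration
#'
#' The shipped operating point of the rhythm-generating network: the
#' printed connection grid plus the calibrated, not-printed values fixed by
#' the package's calibration sweeps ([calibrate_theta()]): spike threshold
#' `theta = 100` controller units, transmitter pulse 24 steps (12 ms),
#' external ON drive 200 units, and the tuned rhythm-frequency strength
#' `P_f = 7000` on the IE to E_dec node.
#'
#' @param mode `"open_loop"` (7-neuron core + follower) or `"closed_loop"`
#'   (adds the three tonic sensor neurons).
#' @param r_bits Fraction width of the bound-receptor storage format.
#' @param backend `"fixed"` or `"float"`.
#' @param P_f Tuned strength of the IE to E_dec connection.
#' @param theta,pulse_steps,ext_on Calibrated LIF/drive values.
#' @param include_follower Include the I_inc follower (required to produce
#'   a stimulation drive; default TRUE).
#' @return List with `roster`, `net` (compiled), `ext_on`, `mode`, and the
#'   encoder configs for the closed loop.
#' @export
reference_config <- function(mode = c("open_loop", "closed_loop"),
                             r_bits = 18, backend = "fixed",
                             P_f = NULL, theta = 100, pulse_steps = 24,
                             ext_on = 200, include_follower = TRUE,
                             tonic = NULL, follower = NULL,
                             vol_encoder = NULL,
                             co2_encoder = encoder_cfg(v_min = 0.02, v_max = 0.2,
                                                       f_max = 300)) {
  mode <- match.arg(mode)
  # tuned rhythm-frequency strength: the autonomous open-loop rhythm needs
  # the higher value to sit in the eupneic band; the volume-entrained closed
  # loop runs at the printed grid value
  if (is.null(P_f)) P_f <- if (mode == "open_loop") 7000 else 5000
  if (is.null(follower)) {
    # open loop: the EI-triggered follower paces the stimulation burst; in
    # closed loop that route is a subthreshold bias and the volume-gated
    # line (Vol_to_Iinc) carries the trigger, so the stimulation amplifies
    # the native inspiratory effort in phase
    follower <- if (mode == "open_loop") {
      list(EI_to_Iinc = 1280, Edec_to_Iinc = -1500, Iinc_self = 80)
    } else {
      # strictly subthreshold bias (max 0.92 * 100 < theta): the volume-gated
      # line must carry the trigger so stimulation stays inspiration-phased
      list(EI_to_Iinc = 100, Edec_to_Iinc = -1500, Iinc_self = 80)
    }
  }
  if (is.null(vol_encoder)) {
    vol_encoder <- encoder_cfg(v_min = 1.1, v_max = 1.9, f_max = 500)
  }
  ros <- build_open_loop(include_follower = include_follower,
                         follower = follower)
  ros$connections$P[ros$connections$plastic_tag == "P_f"] <- P_f
  if (mode == "closed_loop") {
    ros <- if (is.null(tonic)) build_closed_loop(ros)
           else build_closed_loop(ros, tonic = tonic)
  }
  lif <- lif_params(theta = theta, pulse_steps = pulse_steps)
  net <- compile_network(ros, lif = lif,
                         fp = fixedpoint_params(r_bits = r_bits),
                         backend = backend)
  list(
    mode = mode, roster = ros, net = net, ext_on = ext_on,
    vol_encoder = vol_encoder,
    co2_encoder = co2_encoder
  )
}

#' Reference plasticity rules for the closed loop
#'
#' One rule per adapted strength: the rhythm-frequency node P_f
#' (IE to E_dec) and the amplitude node P_a (the volume-gated follower
#' drive), each with its own clamp range around the calibrated operating
#' point. Magnitudes are package calibration values.
#'
#' @return List of [plasticity_rule()] objects.
#' @export
reference_plasticity <- function() {
  list(
    plasticity_rule(a_plus = 0.05, a_minus = 0.05, window_steps = 20,
                    p_min = 4000, p_max = 6000, targets = "P_f"),
    plasticity_rule(a_plus = 0.02, a_minus = 0.02, window_steps = 20,
                    p_min = 40, p_max = 160, targets = "P_a")
  )
}

#' Per-scenario P(inj) strengths
#'
#' The injury-level connections (tagged `P_inj`: the volume and CO2-excess
#' drives onto the inspiratory neuron) are fixed per pair of injury level
#' and metabolic demand rather than learned on-line. Values are package
#' calibration values: support scales up with injury severity and demand.
#'
#' @param wi Weighted injury factor.
#' @param mbc Metabolic demand multiplier.
#' @return Numeric vector in roster order of the `P_inj` connections
#'   (C1_spk to I_dec, then the volume-gated follower drive Vol_spk to
#'   I_inc, whose strength grows with injury severity and demand).
#' @export
reference_p_inj <- function(wi, mbc = 1) {
  c(C1_to_Idec = 100 + 250 * (mbc - 1),
    Vol_to_Iinc = max(300, 500 + 3600 * (0.9 - wi) + 400 * (mbc - 1)))
}

#' Experiment scenario description
#'
#' @param name Label.
#' @param wi Weighted injury factor (1 intact, 0 complete injury; the
#'   incomplete-injury studies use 0.9, 0.8, 0.75).
#' @param mbc_schedule data.frame with columns `t_s`, `multiplier`: the
#'   metabolic demand from each time onward (times nondecreasing).
#' @param controller_mode `"off"`, `"open_loop"` or `"closed_loop"`.
#' @param controller_on_t Time (s) the controller switches on.
#' @param duration_s Run length, s.
#' @param seed Integer seed (stochastic encoder variant and noise
#'   fixtures; the core loop is deterministic).
#' @return List of class `scenario`.
#' @export
scenario <- function(name, wi = 1,
                     mbc_schedule = data.frame(t_s = 0, multiplier = 1),
                     controller_mode = c("off", "open_loop", "closed_loop"),
                     controller_on_t = 0, duration_s = 60, seed = 1L) {
  controller_mode <- match.arg(controller_mode)
  stopifnot(duration_s >= 0, !is.unsorted(mbc_schedule$t_s))
  structure(
    list(name = name, wi = wi, mbc_schedule = mbc_schedule,
         controller_mode = controller_mode,
         controller_on_t = controller_on_t,
         duration_s = duration_s, seed = as.integer(seed)),
    class = "scenario"
  )
}

#' The six reference injury/metabolic-demand pairs
#'
#' @return data.frame of the six pairs: wi in \{0.9, 0.8, 0.75\} crossed
#'   with metabolic demand +11% and +17%.
#' @export
reference_pairs <- function() {
  expand.grid(wi = c(0.9, 0.8, 0.75), mbc = c(1.11, 1.17))
}

#' Run one closed-loop (or open-loop, or controller-off) scenario
#'
#' Per step: plant sensors are encoded into tonic spike trains (closed
#' loop) or the external ON drive is applied (open loop); the network
#' advances one step (with on-line plasticity on the tagged connections in
#' closed loop); the follower's trailing-20-step spike count becomes the
#' stimulation ratio; native and stimulated activation are combined and
#' drive the lung mechanics; CO2 metabolism and the breath-by-breath
#' dynamical respiratory rate close the physiological loop.
#'
#' @param sc A [scenario()].
#' @param plant Calibrated [plant_params()].
#' @param cfg A [reference_config()] matching the scenario's controller
#'   mode (ignored when the controller is off).
#' @param plasticity A [plasticity_rule()] or NULL to disable adaptation.
#' @param p_inj Optional named numeric: per-scenario overrides of the
#'   strengths tagged `P_inj` (names ignored; applied in roster order).
#' @param force_zero_stim Run the full controller but deliver zero drive to
#'   the plant (for the OFF/ON consistency checks).
#' @param record_spikes Also return the full spike raster (memory-heavy).
#' @return List: per-step traces `time_s`, `volume`, `co2`, `stim`,
#'   `native`, `activation`, `P_f` (strength trajectory), breath `records`,
#'   `summary`, and final states.
#' @export
run_scenario <- function(sc, plant, cfg = NULL, plasticity = NULL,
                         p_inj = NULL, force_zero_stim = FALSE,
                         record_spikes = FALSE) {
  dt <- plant$dt
  n <- round(sc$duration_s / dt)
  use_net <- sc$controller_mode != "off"
  if (use_net) {
    stopifnot(!is.null(cfg))
    if (abs(cfg$net$lif$dt - dt) > 1e-12) {
      stop("run_scenario: controller and plant dt differ")
    }
    net <- cfg$net
    if (!is.null(p_inj)) {
      idx <- which(net$conn$plastic_tag == "P_inj")
      if (length(idx) != length(p_inj)) {
        stop("p_inj length does not match the roster's P_inj connections")
      }
      net$P[idx] <- as.numeric(p_inj)
      if (net$backend == "fixed") net$P_raw[idx] <- round(net$P[idx])
    }
    ns <- snn_init_state(net)
    on_i <- match("ON", net$neurons)
    iinc_i <- match("I_inc", net$neurons)
    if (is.na(iinc_i)) stop("run_scenario: roster lacks the I_inc follower")
    closed <- sc$controller_mode == "closed_loop"
    if (closed) {
      vol_i <- match("Vol_spk", net$neurons)
      c1_i <- match("C1_spk", net$neurons)
      c2_i <- match("C2_spk", net$neurons)
      if (anyNA(c(vol_i, c1_i, c2_i))) {
        stop("closed-loop scenario needs the tonic sensor neurons")
      }
      enc_vol <- encoder_init()
      enc_co2 <- list(c1 = encoder_init(), c2 = encoder_init())
    }
    # plastic connection bookkeeping (one or several rules, each with its
    # own targets and clamp range)
    rules <- if (inherits(plasticity, "plasticity_rule")) list(plasticity)
             else plasticity
    do_plast <- closed && length(rules) > 0
    if (do_plast) {
      p_idx <- integer(0); p_rule <- integer(0)
      for (ri in seq_along(rules)) {
        idx <- which(net$conn$plastic_tag %in% rules[[ri]]$targets)
        p_idx <- c(p_idx, idx); p_rule <- c(p_rule, rep(ri, length(idx)))
      }
      p_pre <- net$pre_idx[p_idx]; p_post <- net$post_idx[p_idx]
    }
    pf_idx <- which(net$conn$plastic_tag == "P_f")[1]
  }
  set.seed(sc$seed)
  st <- plant_init_state(plant, sched_mbc(sc$mbc_schedule, 0))
  on_steps <- round(sc$controller_on_t / dt)

  volume <- numeric(n); co2 <- numeric(n); stim_tr <- numeric(n)
  native_tr <- numeric(n); act_tr <- numeric(n); pf_tr <- numeric(n)
  raster <- if (use_net && record_spikes) matrix(0L, n, length(net$neurons),
                                                 dimnames = list(NULL, net$neurons))

  # hot loop: the plant state and encoder accumulators are kept in local
  # scalars (arithmetic identical to lung_step/metabolism_step/phase_step
  # and encoder_step; the OFF-mode trace equality with run_plant is pinned
  # by a test)
  x <- st$x; xd <- st$xd; vol <- st$volume
  co2v <- st$co2; co2s <- st$co2_slow
  phase <- st$phase; rr_cur <- st$rr_current; f_corr <- st$f_corr
  co2_prod <- 0; co2_clr <- 0; br_sum <- 0; br_steps <- 0L; breaths <- 0L
  if (use_net && closed) {
    acc_v <- 0; acc_c1 <- 0; acc_c2 <- 0
    vcfg <- cfg$vol_encoder; ccfg <- cfg$co2_encoder
  }
  insp_frac <- plant$insp_frac
  rec_den <- 1 - exp(-plant$k_rec)
  pf_cur <- if (use_net) net$P[pf_idx] else NA_real_
  # per-step metabolic demand, precomputed from the schedule
  mbc_steps <- sc$mbc_schedule$multiplier[
    pmax(findInterval((seq_len(n) - 1) * dt, sc$mbc_schedule$t_s), 1)]
  if (use_net && !closed) {
    ext_on_vec <- numeric(length(net$neurons))
    ext_on_vec[on_i] <- cfg$ext_on
  }
  n_neur <- if (use_net) length(net$neurons) else 0L

  for (i in seq_len(n)) {
    m <- mbc_steps[i]
    ctrl_on <- use_net && i > on_steps
    stim <- 0
    if (use_net) {
      ext <- NULL; fs <- NULL
      if (ctrl_on) {
        if (closed) {
          fs <- logical(n_neur)
          f <- vcfg$f_max * min(max((vol - vcfg$v_min) / (vcfg$v_max - vcfg$v_min), 0), 1)
          acc_v <- acc_v + f * dt
          if (acc_v >= 1) { fs[vol_i] <- TRUE; acc_v <- acc_v - 1 }
          rel <- (co2s - plant$co2_base) / plant$co2_base
          f1 <- ccfg$f_max * min(max((rel - ccfg$v_min) / (ccfg$v_max - ccfg$v_min), 0), 1)
          f2 <- ccfg$f_max * min(max((-rel - ccfg$v_min) / (ccfg$v_max - ccfg$v_min), 0), 1)
          acc_c1 <- acc_c1 + f1 * dt
          if (acc_c1 >= 1) { fs[c1_i] <- TRUE; acc_c1 <- acc_c1 - 1 }
          acc_c2 <- acc_c2 + f2 * dt
          if (acc_c2 >= 1) { fs[c2_i] <- TRUE; acc_c2 <- acc_c2 - 1 }
        } else {
          ext <- ext_on_vec
        }
      }
      if (do_plast && ctrl_on) pre_cnt <- ns$hist_cnt  # window counts before this step
      ns <- network_step(net, ns, ext_tpp = ext, forced_spikes = fs)
      if (do_plast && ctrl_on && any(ns$spike[c(p_pre, p_post)] == 1L)) {
        for (k in seq_along(p_idx)) {
          j <- p_idx[k]
          newP <- stdp_step(net$P[j], ns$spike[p_pre[k]], ns$spike[p_post[k]],
                            pre_cnt[p_pre[k]], pre_cnt[p_post[k]],
                            rules[[p_rule[k]]])
          if (newP != net$P[j]) {
            net$P[j] <- newP
            if (net$backend == "fixed") net$P_raw[j] <- round(newP)
          }
        }
        pf_cur <- net$P[pf_idx]
      }
      if (ctrl_on) stim <- ns$hist_cnt[iinc_i] / 20
      if (record_spikes) raster[i, ] <- ns$spike
    }
    if (force_zero_stim) stim <- 0

    # native drive + activation
    nat <- if (phase < insp_frac) sc$wi * (phase / insp_frac) else 0
    a <- nat + stim; if (a > 1) a <- 1
    # lung mechanics
    rec_f <- if (plant$k_rec <= 0) a else (1 - exp(-plant$k_rec * a)) / rec_den
    Fm <- plant$F_max * rec_f
    k_spring <- plant$k0 * (1 + plant$k_nl * max(0, x - plant$x_knee))
    xdd <- (Fm - plant$damping * xd - k_spring * x) / plant$mass
    xd <- xd + dt * xdd
    x <- x + dt * xd
    vol_new <- plant$vol_gain * x
    exh <- max(0, vol - vol_new)
    vol <- vol_new
    # metabolism
    prod <- m * plant$mbc0 * dt
    clear <- min(plant$k_ex * exh * co2v, co2v + prod)
    co2v <- co2v + prod - clear
    co2s <- co2s + dt / plant$co2_sensor_tau * (co2v - co2s)
    co2_prod <- co2_prod + prod; co2_clr <- co2_clr + clear
    br_sum <- br_sum + co2v; br_steps <- br_steps + 1L
    # phase + dynamical RR
    phase <- phase + rr_cur / 60 * dt
    if (phase >= 1) {
      phase <- phase - 1
      breaths <- breaths + 1L
      if (br_steps > 0L) {
        err <- (br_sum / br_steps - plant$co2_base) / plant$co2_base
        f_corr <- min(max(f_corr + plant$rr_gain * err, plant$f_corr_bounds[1]),
                      plant$f_corr_bounds[2])
      }
      rr_cur <- dynamical_rr(m, plant$rr_reg) * f_corr
      br_sum <- 0; br_steps <- 0L
    }

    volume[i] <- vol; co2[i] <- co2v; stim_tr[i] <- stim
    native_tr[i] <- nat; act_tr[i] <- a
    pf_tr[i] <- pf_cur
  }

  st <- list(x = x, xd = xd, volume = vol, co2 = co2v, co2_slow = co2s,
             phase = phase, rr_current = rr_cur, f_corr = f_corr,
             co2_produced = co2_prod, co2_cleared = co2_clr,
             breath_co2_sum = br_sum, breath_steps = br_steps,
             breaths = breaths)

  records <- segment_breaths(volume, dt)
  out <- list(
    scenario = sc,
    time_s = seq_len(n) * dt,
    volume = volume, co2 = co2, stim = stim_tr,
    native = native_tr, activation = act_tr, P_f = pf_tr,
    records = records,
    summary = if (nrow(records) > 0) breath_summary(records) else NULL,
    plant_state = st,
    net_state = if (use_net) ns else NULL,
    net_P = if (use_net) net$P else NULL
  )
  if (use_net && record_spikes) out$raster <- raster
  out
}

sched_mbc <- function(schedule, t) {
  i <- findInterval(t, schedule$t_s)
  if (i < 1) i <- 1
  schedule$multiplier[i]
}

#' Steady respiratory rate of the autonomous (complete-injury) rhythm
#'
#' Runs the open-loop controller on the complete-injury plant (native drive
#' zero) and reports the steady RR of the stimulated volume trace.
#'
#' @param cfg [reference_config()] (open loop).
#' @param plant Calibrated plant parameters.
#' @param duration_s Run length.
#' @return Mean RR over the trailing 10 breaths (breaths/min), NA when
#'   fewer than 12 breaths were produced.
#' @export
open_loop_rr <- function(cfg, plant, duration_s = 30) {
  sc <- scenario("complete-injury open loop", wi = 0,
                 controller_mode = "open_loop", duration_s = duration_s)
  run <- run_scenario(sc, plant, cfg)
  rec <- run$records
  if (nrow(rec) < 12) return(NA_real_)
  mean(utils::tail(rec$rr, 10))
}

#' Bit-width accuracy study
#'
#' Sweeps the bound-receptor storage width and the rhythm-frequency
#' strength P_f on the complete-injury open-loop configuration and reports
#' the steady RR per (width, P_f), plus each width's maximum absolute RR
#' deviation from the widest (reference) format.
#'
#' @param plant Calibrated plant parameters.
#' @param fraction_bits Widths to sweep (reference = last/maximum).
#' @param pf_values P_f values to sweep.
#' @param duration_s Run length per cell.
#' @return List: `rr` matrix (widths x P_f), `max_dev` named vector of
#'   max |RR(width) - RR(ref)|, `ref_bits`.
#' @export
bit_accuracy_sweep <- function(plant, fraction_bits = c(16, 18, 20, 32),
                               pf_values = c(6000, 6500, 7000),
                               duration_s = 30) {
  fraction_bits <- sort(fraction_bits)
  rr <- matrix(NA_real_, length(fraction_bits), length(pf_values),
               dimnames = list(paste0("b", fraction_bits), paste0("P", pf_values)))
  for (bi in seq_along(fraction_bits)) {
    for (pj in seq_along(pf_values)) {
      cfg <- reference_config("open_loop", r_bits = fraction_bits[bi],
                              P_f = pf_values[pj], backend = "fixed")
      rr[bi, pj] <- open_loop_rr(cfg, plant, duration_s)
    }
  }
  ref <- nrow(rr)
  max_dev <- apply(abs(sweep(rr, 2, rr[ref, ])), 1, max)
  list(rr = rr, max_dev = max_dev, ref_bits = fraction_bits[ref])
}

#' Generate synthetic reference waveforms and test rasters
#'
#' Produces the eupneic reference volume trace (56 breaths/min, 2 mL,
#' sawtooth-driven through the calibrated plant), a noisy variant, and
#' small deterministic spike rasters for unit tests. All randomness flows
#' from `seed`.
#'
#' @param plant Calibrated plant parameters.
#' @param seed Integer seed.
#' @param duration_s Trace length.
#' @param noise_frac Additive Gaussian noise amplitude as a fraction of the
#'   tidal volume.
#' @return List: `time_s`, `volume`, `volume_noisy`, `raster` (20 x 5
#'   matrix of hand-checkable spike bits), `seed`.
#' @export
generate_fixtures <- function(plant, seed = 1L, duration_s = 20,
                              noise_frac = 0.01) {
  set.seed(seed)
  run <- run_plant(plant, wi = 1, mbc = 1, duration_s = duration_s,
                   dynamic_rr = FALSE)
  noisy <- run$volume + stats::rnorm(length(run$volume),
                                     sd = noise_frac * plant$vt0)
  raster <- matrix(0L, 20, 5, dimnames = list(NULL, paste0("n", 1:5)))
  raster[cbind(c(1, 5, 9, 13, 17), c(1, 2, 3, 4, 5))] <- 1L
  raster[, 5] <- rep(c(1L, 0L), 10)
  list(time_s = run$time_s, volume = run$volume, volume_noisy = noisy,
       raster = raster, seed = seed)
}

#' Calibrate the spike threshold of a network configuration
#'
#' Grid sweep over candidate thresholds: for each, the complete-injury
#' open-loop rhythm is simulated and its rate and regularity measured; the
#' smallest threshold giving a stable rhythm (CV below `cv_max`) with RR
#' inside `band` is returned, or, if the band is not attainable, the
#' stable threshold whose RR is closest to the band.
#'
#' @param plant Calibrated plant parameters.
#' @param thetas Candidate thresholds.
#' @param band Target RR band, breaths/min (the rat eupneic range).
#' @param cv_max Stability criterion on the CV of RR, percent.
#' @param pulse_steps,P_f Remaining reference operating point values.
#' @param duration_s Run length per candidate.
#' @return List: `theta` (selected), `table` (theta, RR, CV), `in_band`.
#' @export
calibrate_theta <- function(plant, thetas = c(80, 100, 120, 140),
                            band = c(56, 67), cv_max = 5,
                            pulse_steps = 24, P_f = 7000,
                            duration_s = 30) {
  tab <- data.frame(theta = thetas, rr = NA_real_, cv = NA_real_)
  for (i in seq_along(thetas)) {
    cfg <- reference_config("open_loop", theta = thetas[i],
                            pulse_steps = pulse_steps, P_f = P_f,
                            backend = "fixed")
    sc <- scenario("theta calibration", wi = 0, controller_mode = "open_loop",
                   duration_s = duration_s)
    run <- run_scenario(sc, plant, cfg)
    rec <- run$records
    if (nrow(rec) >= 12) {
      tab$rr[i] <- mean(utils::tail(rec$rr, 10))
      tab$cv[i] <- cv_rr(rec)
    }
  }
  stable <- !is.na(tab$rr) & tab$cv < cv_max
  in_band <- stable & tab$rr >= band[1] & tab$rr <= band[2]
  sel <- if (any(in_band)) {
    which(in_band)[1]
  } else if (any(stable)) {
    cand <- which(stable)
    cand[which.min(pmax(band[1] - tab$rr[cand], tab$rr[cand] - band[2], 0))]
  } else {
    stop("calibrate_theta: no stable rhythm on the candidate grid")
  }
  list(theta = tab$theta[sel], table = tab, in_band = any(in_band))
}

#' Write run traces as tidy CSV
#'
#' One row per millisecond (2x downsampled from the 0.5 ms step) with
#' columns time_s, volume_mL, co2, native, stim, activation.
#'
#' @param run Output of [run_scenario()].
#' @param path Output file.
#' @param full_rate Write every step instead of downsampling.
#' @export
write_trace_csv <- function(run, path, full_rate = FALSE) {
  idx <- if (full_rate) seq_along(run$time_s) else seq(2, length(run$time_s), by = 2)
  df <- data.frame(
    time_s = run$time_s[idx], volume_mL = run$volume[idx],
    co2 = run$co2[idx], native = run$native[idx],
    stim = run$stim[idx], activation = run$activation[idx]
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' @param run Output of [run_scenario()].
#' @param path Output file.
#' @export
write_summary_json <- function(run, path) {
  s <- run$summary
  s$scenario <- run$scenario$name
  s$schema_version <- 1L
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
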