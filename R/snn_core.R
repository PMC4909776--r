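# Discrete-time spiking neural network core.
#
# The controller is a small network of leaky integrate-and-fire (LIF) neurons
# coupled by a two-branch kinetic synapse model tracking the fraction of
# bound receptors r(t) per connection. Everything advances on a fixed 0.5 ms
# step (2 kHz). Each step has two phases, mirroring the hardware sequencer:
#   phase 1 ("kinetic")  : every r is updated from the spike bits of the
#                          previous step;
#   phase 2 ("spike")    : every neuron's total postsynaptic potential (TPP)
#                          is computed from the phase-1 r values, then the
#                          membrane displacement, refractory status and spike
#                          bit are updated.
# No value written in a phase is read in the same phase, so update order
# within a phase cannot affect the result.

#' Derive discrete-time kinetic constants from binding rates
#'
#' The kinetic synapse model has a rising branch while the presynaptic
#' neuron's transmitter pulse is on, `r' = B*r + A`, and a decay branch
#' otherwise, `r' = C*r`, the forward-Euler discretization of
#' `dr/dt = alpha*(1-r) - beta*r` (rising) and `dr/dt = -beta*r` (decay):
#' `A = dt*alpha`, `B = 1 - dt*(alpha+beta)`, `C = 1 - dt*beta`.
#' The rising-branch fixed point `A/(1-B)` equals the steady-state bound
#' fraction `r_inf = alpha/(alpha+beta)` and the rise time constant is
#' `tau_r = 1/(alpha+beta)`.
#'
#' @param alpha Forward (binding) rate constant, 1/s. Non-negative.
#' @param beta Backward (unbinding) rate constant, 1/s. Positive.
#' @param dt Time step in seconds (default 0.5 ms).
#' @return List with `r_inf`, `tau_r_ms`, `A`, `B`, `C`.
#' @examples
#' derive_kinetic_constants(900, 100)  # A = 0.45, B = 0.50, C = 0.95
#' @export
derive_kinetic_constants <- function(alpha, beta, dt = 5e-4) {
  stopifnot(alpha >= 0, beta > 0, dt > 0)
  if (dt * (alpha + beta) >= 1) {
    stop(sprintf(
      "unstable kinetic set: dt*(alpha+beta) = %.3f >= 1 for alpha=%g, beta=%g",
      dt * (alpha + beta), alpha, beta
    ))
  }
  list(
    r_inf = alpha / (alpha + beta),
    tau_r_ms = 1000 / (alpha + beta),
    A = dt * alpha,
    B = 1 - dt * (alpha + beta),
    C = 1 - dt * beta
  )
}

#' Reference table of kinetic parameter sets
#'
#' The five synapse kinetics available to connections, ordered from slow
#' (set 1, rise time constant 15.9 ms) to fast (set 5, 1 ms). Rates are in
#' 1/s; the discrete constants A, B, C are derived for the 0.5 ms step.
#'
#' @param dt Time step in seconds.
#' @return A data.frame with columns `set`, `alpha`, `beta`, `r_inf`,
#'   `tau_r_ms`, `A`, `B`, `C`.
#' @export
kinetic_table <- function(dt = 5e-4) {
  rates <- data.frame(
    set = 1:5,
    alpha = c(58, 115, 230, 450, 900),
    beta = c(5, 10, 20, 50, 100)
  )
  k <- lapply(seq_len(nrow(rates)), function(i) {
    derive_kinetic_constants(rates$alpha[i], rates$beta[i], dt)
  })
  cbind(rates, do.call(rbind, lapply(k, as.data.frame)))
}

#' Pure kinetic synapse update (single branch selection)
#'
#' One discrete step of the bound-receptor fraction. Vectorized over
#' connections; `pre_spiking` selects the rising branch.
#'
#' @param r Current bound-receptor fractions in \[0, 1\].
#' @param pre_spiking Logical vector: transmitter pulse on for this step.
#' @param k List or data.frame row(s) with fields `A`, `B`, `C` (recycled).
#' @return Updated fractions, clamped to \[0, 1\].
#' @export
kinetic_step <- function(r, pre_spiking, k) {
  stopifnot(all(r >= 0 & r <= 1))
  out <- ifelse(pre_spiking, k$B * r + k$A, k$C * r)
  pmin(pmax(out, 0), 1)
}

#' Default LIF / datapath parameters
#'
#' @param theta Spike threshold on the membrane displacement, controller
#'   units. The reference value is fixed by [calibrate_theta()].
#' @param leak_shift The leak ratio tau_m/dt as a power of two: the membrane
#'   relaxes by `(tpp - v)/2^leak_shift` per step (default 3, i.e. 1/8).
#' @param refractory_steps Minimum refractory time in steps (default 1).
#' @param dt Step in seconds.
#' @param pulse_steps Transmitter-pulse length: number of steps the rising
#'   branch stays on after a presynaptic spike (default 1).
#' @return List of LIF parameters.
#' @export
lif_params <- function(theta = 600, leak_shift = 3, refractory_steps = 1,
                       dt = 5e-4, pulse_steps = 1) {
  stopifnot(theta > 0, leak_shift >= 0, refractory_steps >= 1, pulse_steps >= 1)
  list(theta = theta, leak_shift = as.integer(leak_shift),
       refractory_steps = as.integer(refractory_steps), dt = dt,
       pulse_steps = as.integer(pulse_steps))
}

#' Default fixed-point formats for the datapath
#'
#' `r_format` stores the bound-receptor fractions (reference: U0.18),
#' `k_format` the kinetic constants A, B, C (U0.14), and `v_format` the
#' membrane displacement. The membrane format keeps the same fraction width
#' as `r_format` with 16 integer bits of headroom, enough that the largest
#' reference strength (|P| = 8000) at r = 1 cannot overflow an 8-term
#' accumulation; sums saturate rather than wrap.
#'
#' @param r_bits Fraction width for r (16--32 in the accuracy study).
#' @param k_bits Fraction width for the kinetic constants.
#' @param v_int_bits Integer headroom bits of the membrane format.
#' @return List of `fixed_format` objects `r_format`, `k_format`, `v_format`.
#' @export
fixedpoint_params <- function(r_bits = 18, k_bits = 14, v_int_bits = 16) {
  stopifnot(r_bits >= k_bits)
  list(
    r_format = fixed_format(0, r_bits, signed = FALSE),
    k_format = fixed_format(0, k_bits, signed = FALSE),
    v_format = fixed_format(v_int_bits, r_bits, signed = TRUE)
  )
}

#' Compile a network roster into a runnable network
#'
#' Validates the roster (kinetic indices, fan-in limit) and precomputes the
#' per-connection constants for the chosen backend.
#'
#' @param roster A [network_roster()] (neurons + connections).
#' @param lif LIF parameters from [lif_params()].
#' @param fp Fixed-point formats from [fixedpoint_params()]; used by the
#'   `"fixed"` backend.
#' @param backend `"fixed"` for the bit-faithful datapath, `"float"` for the
#'   double-precision oracle.
#' @param kinetics Kinetic table (default [kinetic_table()] at `lif$dt`).
#' @param max_fan_in Hard limit on incoming connections per neuron
#'   (default 8, the hardware constraint). Violations are an error.
#' @return An object of class `snn_network`.
#' @export
compile_network <- function(roster, lif = lif_params(),
                            fp = fixedpoint_params(),
                            backend = c("fixed", "float"),
                            kinetics = kinetic_table(lif$dt),
                            max_fan_in = 8) {
  backend <- match.arg(backend)
  neurons <- roster$neurons
  conn <- roster$connections
  n <- length(neurons)
  stopifnot(n >= 1)
  pre_idx <- match(conn$pre, neurons)
  post_idx <- match(conn$post, neurons)
  if (anyNA(pre_idx) || anyNA(post_idx)) {
    stop("connection endpoints must name roster neurons")
  }
  if (!all(conn$kinetic %in% kinetics$set)) {
    stop("unknown kinetic set index in connections")
  }
  fan_in <- tabulate(post_idx, nbins = n)
  if (any(fan_in > max_fan_in)) {
    stop(sprintf("fan-in limit exceeded: neuron %s has %d incoming connections (max %d)",
                 neurons[which.max(fan_in)], max(fan_in), max_fan_in))
  }
  krow <- match(conn$kinetic, kinetics$set)
  A <- kinetics$A[krow]; B <- kinetics$B[krow]; C <- kinetics$C[krow]

  net <- list(
    backend = backend,
    neurons = neurons,
    n_neurons = n,
    conn = conn,
    n_conn = nrow(conn),
    pre_idx = pre_idx,
    post_idx = post_idx,
    P = as.numeric(conn$P),
    lif = lif,
    fp = fp,
    kinetics = kinetics,
    # dense incidence matrix post-neuron x connection for the TPP sum
    M = {
      M <- matrix(0, n, nrow(conn))
      M[cbind(post_idx, seq_len(nrow(conn)))] <- 1
      M
    }
  )
  if (backend == "fixed") {
    kf <- fp$k_format; rf <- fp$r_format; vf <- fp$v_format
    net$A_raw <- quantize(A, kf)$raw
    net$B_raw <- quantize(B, kf)$raw
    net$C_raw <- quantize(C, kf)$raw
    # A aligned to the r format for the rising-branch addition
    net$A_in_r <- net$A_raw * 2^(rf$fraction_bits - kf$fraction_bits)
    net$theta_raw <- ceiling(lif$theta * 2^vf$fraction_bits)
    # P carried as exact signed integers scaled into the v format
    net$P_raw <- round(net$P)
  } else {
    net$A_f <- A; net$B_f <- B; net$C_f <- C
  }
  class(net) <- "snn_network"
  net
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network: %d neurons, %d connections, backend=%s>\n",
              x$n_neurons, x$n_conn, x$backend))
  invisible(x)
}

#' Initial all-quiescent network state
#'
#' @param net A compiled `snn_network`.
#' @return A state list: membrane displacements (`v` real or `v_raw`),
#'   per-connection bound fractions (`r` or `r_raw`), spike bits, transmitter
#'   pulse gates, refractory counters, 20-step spike-history ring buffer and
#'   its running counts, and the step counter `t`.
#' @export
snn_init_state <- function(net) {
  n <- net$n_neurons
  st <- list(
    spike = integer(n),
    gate = integer(n),          # transmitter-pulse steps remaining, per neuron
    refr = integer(n),          # refractory steps remaining
    hist = matrix(0L, n, 20),   # ring buffer of the last 20 spike bits
    hist_ptr = 1L,
    hist_cnt = integer(n),      # running popcount of the window
    t = 0L
  )
  if (net$backend == "fixed") {
    st$r_raw <- numeric(net$n_conn)
    st$v_raw <- numeric(n)
  } else {
    st$r <- numeric(net$n_conn)
    st$v <- numeric(n)
  }
  st
}

#' Advance the network by one 0.5 ms step
#'
#' Phase 1 updates every connection's bound-receptor fraction from the
#' transmitter-pulse gates set by the previous step's spikes; phase 2 sums
#' each neuron's TPP and updates membrane, refractory state and spike bit.
#'
#' @param net Compiled network.
#' @param state State from [snn_init_state()] or a previous step.
#' @param ext_tpp Optional numeric vector (length `n_neurons`) of external
#'   input added to the TPP this step, controller units.
#' @param forced_spikes Optional logical/0-1 vector: neurons whose spike bit
#'   is driven externally this step (sensor-encoded tonic neurons). Their
#'   membrane is held at rest.
#' @return The updated state.
#' @export
network_step <- function(net, state, ext_tpp = NULL, forced_spikes = NULL) {
  lif <- net$lif
  pulse_on <- state$gate[net$pre_idx] > 0L
  on_idx <- which(pulse_on)

  if (net$backend == "fixed") {
    vf <- net$fp$v_format
    drop <- 2^net$fp$k_format$fraction_bits
    r <- state$r_raw
    r_new <- floor(net$C_raw * r / drop)
    if (length(on_idx)) {
      r_new[on_idx] <- floor(net$B_raw[on_idx] * r[on_idx] / drop) +
        net$A_in_r[on_idx]
    }
    rmax <- net$fp$r_format$raw_max
    r_new[r_new > rmax] <- rmax
    r_new[r_new < 0] <- 0
    state$r_raw <- r_new

    # phase 2: TPP in v-format raw units (P integer times r raw is exact)
    tpp_raw <- net$M %*% (net$P_raw * r_new)
    dim(tpp_raw) <- NULL
    if (!is.null(ext_tpp)) tpp_raw <- tpp_raw + round(ext_tpp * 2^vf$fraction_bits)
    tpp_raw[tpp_raw > vf$raw_max] <- vf$raw_max
    tpp_raw[tpp_raw < vf$raw_min] <- vf$raw_min
    v <- state$v_raw
    v_new <- v + floor((tpp_raw - v) / 2^lif$leak_shift)
    v_new[v_new > vf$raw_max] <- vf$raw_max
    v_new[v_new < vf$raw_min] <- vf$raw_min
    in_refr <- state$refr > 0L
    v_new[in_refr] <- 0
    spike <- as.integer(!in_refr & v_new >= net$theta_raw)
    state$v_raw <- v_new
  } else {
    r <- state$r
    r_new <- net$C_f * r
    if (length(on_idx)) {
      r_new[on_idx] <- net$B_f[on_idx] * r[on_idx] + net$A_f[on_idx]
    }
    r_new[r_new > 1] <- 1
    r_new[r_new < 0] <- 0
    state$r <- r_new

    tpp <- net$M %*% (net$P * r_new)
    dim(tpp) <- NULL
    if (!is.null(ext_tpp)) tpp <- tpp + ext_tpp
    v <- state$v
    v_new <- v + (tpp - v) / 2^lif$leak_shift
    in_refr <- state$refr > 0L
    v_new[in_refr] <- 0
    spike <- as.integer(!in_refr & v_new >= lif$theta)
    state$v <- v_new
  }

  if (!is.null(forced_spikes)) {
    forced <- which(forced_spikes != 0)
    if (length(forced)) {
      spike[forced] <- 1L
      if (net$backend == "fixed") state$v_raw[forced] <- 0
      else state$v[forced] <- 0
    }
  }

  # refractory bookkeeping: decrement, then arm for spiking neurons
  refr <- state$refr - 1L
  refr[refr < 0L] <- 0L
  sp_idx <- which(spike == 1L)
  refr[sp_idx] <- lif$refractory_steps
  state$refr <- refr
  state$spike <- spike
  # transmitter pulse gates for the next kinetic phase
  gate <- state$gate - 1L
  gate[gate < 0L] <- 0L
  gate[sp_idx] <- lif$pulse_steps
  state$gate <- gate

  # 20-step spike history ring buffer and running counts
  ptr <- state$hist_ptr
  old <- state$hist[, ptr]
  state$hist[, ptr] <- spike
  state$hist_cnt <- state$hist_cnt + spike - old
  state$hist_ptr <- if (ptr == 20L) 1L else ptr + 1L

  state$t <- state$t + 1L
  state
}

#' Run a compiled network and record probe traces
#'
#' @param net Compiled network.
#' @param n_steps Number of 0.5 ms steps (2000 steps = 1 s).
#' @param probes Character vector of neuron names to record (`v`, `spike`)
#'   or `"*"` for all. Unknown names are an error.
#' @param probe_r Integer vector of connection indices whose bound fraction
#'   is recorded (default none).
#' @param ext_tpp_fun Optional `function(step)` returning the external TPP
#'   vector for that step.
#' @param forced_spikes_fun Optional `function(step)` returning the forced
#'   spike vector for that step.
#' @param state Optional starting state (default quiescent).
#' @return List with `time_s`, matrices `v` and `spike`
#'   (steps x probed neurons), `r` (steps x probed connections), and the
#'   final `state`.
#' @export
run_network <- function(net, n_steps, probes = "*", probe_r = integer(0),
                        ext_tpp_fun = NULL, forced_spikes_fun = NULL,
                        state = NULL) {
  stopifnot(n_steps >= 1)
  if (identical(probes, "*")) probes <- net$neurons
  unknown <- setdiff(probes, net$neurons)
  if (length(unknown)) stop("unknown probe neuron(s): ", paste(unknown, collapse = ", "))
  p_idx <- match(probes, net$neurons)
  if (is.null(state)) state <- snn_init_state(net)

  vmat <- matrix(0, n_steps, length(p_idx), dimnames = list(NULL, probes))
  smat <- matrix(0L, n_steps, length(p_idx), dimnames = list(NULL, probes))
  rmat <- matrix(0, n_steps, length(probe_r))
  vf_scale <- if (net$backend == "fixed") 2^-net$fp$v_format$fraction_bits else 1
  rf_scale <- if (net$backend == "fixed") 2^-net$fp$r_format$fraction_bits else 1

  for (step in seq_len(n_steps)) {
    ext <- if (is.null(ext_tpp_fun)) NULL else ext_tpp_fun(step)
    fs <- if (is.null(forced_spikes_fun)) NULL else forced_spikes_fun(step)
    state <- network_step(net, state, ext_tpp = ext, forced_spikes = fs)
    if (length(p_idx)) {
      vmat[step, ] <- if (net$backend == "fixed") state$v_raw[p_idx] * vf_scale else state$v[p_idx]
      smat[step, ] <- state$spike[p_idx]
    }
    if (length(probe_r)) {
      rmat[step, ] <- if (net$backend == "fixed") state$r_raw[probe_r] * rf_scale else state$r[probe_r]
    }
  }
  list(
    time_s = seq_len(n_steps) * net$lif$dt,
    v = vmat, spike = smat, r = rmat,
    state = state
  )
}

#' Current bound-receptor fractions as real values
#'
#' @param net Compiled network.
#' @param state Network state.
#' @return Numeric vector of r in \[0, 1\], one per connection.
#' @export
network_r <- function(net, state) {
  if (net$backend == "fixed") state$r_raw * 2^-net$fp$r_format$fraction_bits
  else state$r
}

#' Total postsynaptic potential of one neuron
#'
#' The signed sum of `P * r` over a neuron's incoming connections, exposed
#' for inspection and testing (the step loop computes it internally).
#'
#' @param net Compiled network.
#' @param state Network state.
#' @param neuron Neuron name or index.
#' @return TPP in controller units.
#' @export
total_postsynaptic_potential <- function(net, state, neuron) {
  if (is.character(neuron)) neuron <- match(neuron, net$neurons)
  stopifnot(!is.na(neuron), neuron >= 1, neuron <= net$n_neurons)
  incoming <- which(net$post_idx == neuron)
  if (!length(incoming)) return(0)
  sum(net$P[incoming] * network_r(net, state)[incoming])
}
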