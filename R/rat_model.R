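# Computational model of rat breathing (the plant).
#
# Components, all advanced at the controller step (0.5 ms, forward Euler):
#  * native drive: a spaced sawtooth of the breath phase (linear ramp over
#    the inspiratory fraction of the cycle, silent over the rest), attenuated
#    by the weighted injury factor wi;
#  * activation: linear summation of native and stimulated drive, clipped to
#    [0, 1], passed through a monotone mildly-saturating recruitment map to
#    muscle force;
#  * musculoskeletal: damped spring with non-linear (stiffening) stiffness;
#    lung volume is linearly proportional to the diaphragm displacement;
#  * metabolism: CO2 mass produced at a constant rate (scaled by the
#    metabolic demand multiplier mbc) and cleared in proportion to expired
#    flow times the current CO2 amount;
#  * dynamical respiratory rate: a linear RR(mbc) regression plus a
#    breath-by-breath integral correction that holds the CO2 amount at its
#    eupneic baseline.
#
# The eupneic operating point is RR = 56 breaths/min, Vt = 2 mL; the
# calibration routines fix the force scale, the exhalation clearance gain
# and the RR regression to meet it.

#' Plant parameters
#'
#' Defaults describe the pre-calibration model; [calibrate_plant()] returns
#' a copy with `F_max`, `k_ex` and `rr_reg` fixed to the eupneic targets.
#'
#' @param rr0 Eupneic respiratory rate, breaths/min.
#' @param vt0 Eupneic tidal volume, mL.
#' @param insp_frac Inspiratory fraction of the breath cycle (sawtooth ramp
#'   duration as a fraction of the period).
#' @param mass,damping,k0 Spring-mass parameters of the respiratory
#'   mechanics (normalized displacement units); `damping` is chosen near
#'   critical at the small-amplitude stiffness `k0`.
#' @param k_nl,x_knee Non-linear stiffening: stiffness grows by factor
#'   `1 + k_nl*(x - x_knee)` above the knee displacement.
#' @param F_max Force scale mapping full recruitment to spring force
#'   (calibrated).
#' @param vol_gain mL of lung volume per unit diaphragm displacement.
#' @param k_rec Curvature of the saturating recruitment map
#'   `(1 - exp(-k_rec a))/(1 - exp(-k_rec))`; small values are near-linear.
#' @param mbc0 Baseline CO2 production rate (arbitrary mass units per s).
#' @param co2_base Baseline (target) CO2 amount, same units.
#' @param k_ex Exhalation clearance gain, per mL (calibrated).
#' @param co2_sensor_tau Time constant (s) of the low-pass CO2 sensor signal
#'   fed to the chemoreceptor encoders (an end-tidal-like measure that
#'   suppresses the large intra-breath CO2 swing).
#' @param rr_gain Breath-by-breath integral gain of the RR correction on the
#'   relative CO2 error.
#' @param f_corr_bounds Clamp on the RR correction factor.
#' @param rr_reg Numeric `c(a, b)` of the RR = a + b*mbc regression
#'   (calibrated; defaults to RR = rr0*mbc).
#' @param dt Integration step, s.
#' @return List of plant parameters, class `plant_params`.
#' @export
plant_params <- function(rr0 = 56, vt0 = 2, insp_frac = 0.4,
                         mass = 1, damping = 200, k0 = 10000,
                         k_nl = 0.5, x_knee = 0.8,
                         F_max = 11000, vol_gain = 2, k_rec = 0.15,
                         mbc0 = 1, co2_base = 1, k_ex = 0.7,
                         co2_sensor_tau = 3,
                         rr_gain = 0.3, f_corr_bounds = c(0.3, 3),
                         rr_reg = c(0, 56), dt = 5e-4) {
  structure(as.list(environment()), class = "plant_params")
}

#' Native respiratory drive (spaced sawtooth)
#'
#' Linear ramp from 0 to `wi` over the inspiratory fraction of the cycle,
#' zero over the remaining (spaced) fraction. `wi` is the weighted injury
#' factor: 1 intact, 0 complete injury.
#'
#' @param phase Breath phase in \[0, 1).
#' @param wi Weighted injury factor in \[0, 1\].
#' @param insp_frac Inspiratory fraction of the cycle.
#' @return Activation fraction in \[0, wi\].
#' @export
native_drive <- function(phase, wi, insp_frac = 0.4) {
  ramp <- ifelse(phase < insp_frac, phase / insp_frac, 0)
  wi * ramp
}

#' Combine native and stimulated activation
#'
#' Linear summation clipped at full activation.
#'
#' @param native,stim Activation fractions in \[0, 1\].
#' @return `min(native + stim, 1)`.
#' @export
combine_activation <- function(native, stim) {
  pmin(native + stim, 1)
}

#' Recruitment map: activation fraction to normalized muscle force
#'
#' Monotone, mildly saturating static map standing in for the motor-unit
#' recruitment model of the full musculoskeletal chain (not derivable from
#' the printed model description); `rec(0) = 0`, `rec(1) = 1`.
#'
#' @param a Activation in \[0, 1\].
#' @param k_rec Curvature (0 = linear limit).
#' @return Normalized force in \[0, 1\].
#' @export
recruitment <- function(a, k_rec = 0.15) {
  if (k_rec <= 0) return(a)
  (1 - exp(-k_rec * a)) / (1 - exp(-k_rec))
}

#' Initial plant state
#'
#' @param p Plant parameters.
#' @param mbc Initial metabolic demand multiplier.
#' @return List: displacement `x`, velocity `xd`, `volume` (mL), `co2`,
#'   breath `phase`, current rate `rr_current`, RR correction factor
#'   `f_corr`, plus CO2 bookkeeping accumulators.
#' @export
plant_init_state <- function(p, mbc = 1) {
  list(
    x = 0, xd = 0, volume = 0,
    co2 = p$co2_base,
    co2_slow = p$co2_base,
    phase = 0,
    rr_current = dynamical_rr(mbc, p$rr_reg),
    f_corr = 1,
    co2_produced = 0, co2_cleared = 0,
    breath_co2_sum = 0, breath_steps = 0L,
    breaths = 0L
  )
}

#' One step of the lung mechanics
#'
#' Forward-Euler update of the damped spring with non-linear stiffness:
#' `m x'' = F_max*rec(activation) - c x' - k(x) x`, volume = `vol_gain * x`.
#'
#' @param st Plant state.
#' @param p Plant parameters.
#' @param activation Combined activation fraction in \[0, 1\].
#' @return Updated state (with `exhaled_mL` for this step).
#' @export
lung_step <- function(st, p, activation) {
  if (!is.finite(st$x) || !is.finite(st$xd)) stop("lung_step: non-finite state")
  Fm <- p$F_max * recruitment(activation, p$k_rec)
  k_spring <- p$k0 * (1 + p$k_nl * max(0, st$x - p$x_knee))
  xdd <- (Fm - p$damping * st$xd - k_spring * st$x) / p$mass
  st$xd <- st$xd + p$dt * xdd
  st$x <- st$x + p$dt * st$xd
  vol_new <- p$vol_gain * st$x
  st$exhaled_mL <- max(0, st$volume - vol_new)
  st$volume <- vol_new
  st
}

#' One step of the CO2 metabolism
#'
#' Production at rate `mbc * mbc0`; clearance proportional to the expired
#' volume this step times the current CO2 amount (continuous form of
#' per-breath exhalation; per-breath accounting is recovered by
#' integration).
#'
#' @param st Plant state (after [lung_step()], so `exhaled_mL` is current).
#' @param p Plant parameters.
#' @param mbc Metabolic demand multiplier.
#' @return Updated state; `co2` never goes negative and the bookkeeping
#'   accumulators `co2_produced`/`co2_cleared` satisfy
#'   `co2 = co2(0) + produced - cleared` exactly.
#' @export
metabolism_step <- function(st, p, mbc) {
  prod <- mbc * p$mbc0 * p$dt
  clear <- min(p$k_ex * st$exhaled_mL * st$co2, st$co2 + prod)
  st$co2 <- st$co2 + prod - clear
  st$co2_slow <- st$co2_slow + p$dt / p$co2_sensor_tau * (st$co2 - st$co2_slow)
  st$co2_produced <- st$co2_produced + prod
  st$co2_cleared <- st$co2_cleared + clear
  st$breath_co2_sum <- st$breath_co2_sum + st$co2
  st$breath_steps <- st$breath_steps + 1L
  st
}

#' Feed-forward RR from the metabolic demand regression
#'
#' @param mbc Metabolic demand multiplier.
#' @param regression Numeric `c(a, b)`: RR = a + b*mbc (from
#'   [calibrate_rr_regression()]).
#' @return RR in breaths/min.
#' @export
dynamical_rr <- function(mbc, regression) {
  if (is.null(regression) || length(regression) != 2 || any(!is.finite(regression))) {
    stop("dynamical_rr: regression not fitted; run calibrate_rr_regression()")
  }
  regression[[1]] + regression[[2]] * mbc
}

#' Advance the breath phase; apply the dynamical-RR mechanism at boundaries
#'
#' The phase advances at `rr_current/60` cycles per second. At each wrap
#' (breath boundary) the RR correction factor integrates the relative CO2
#' error of the past breath, so the rate settles where clearance balances
#' production at the baseline CO2 amount; rate changes apply only at breath
#' boundaries.
#'
#' @param st Plant state.
#' @param p Plant parameters.
#' @param mbc Metabolic demand multiplier.
#' @param dynamic Apply the breath-by-breath CO2 correction (default TRUE);
#'   with FALSE the rate stays at the regression feed-forward value.
#' @return Updated state.
#' @export
phase_step <- function(st, p, mbc, dynamic = TRUE) {
  st$phase <- st$phase + st$rr_current / 60 * p$dt
  if (st$phase >= 1) {
    st$phase <- st$phase - 1
    st$breaths <- st$breaths + 1L
    if (dynamic && st$breath_steps > 0L) {
      err <- (st$breath_co2_sum / st$breath_steps - p$co2_base) / p$co2_base
      st$f_corr <- min(max(st$f_corr + p$rr_gain * err, p$f_corr_bounds[1]),
                       p$f_corr_bounds[2])
    }
    st$rr_current <- dynamical_rr(mbc, p$rr_reg) * (if (dynamic) st$f_corr else 1)
    st$breath_co2_sum <- 0
    st$breath_steps <- 0L
  }
  st
}

#' Run the plant without a controller
#'
#' Native drive only (or an externally supplied stimulation trace), used by
#' the calibration routines and the controller-OFF arms of the experiments.
#'
#' @param p Plant parameters.
#' @param wi Weighted injury factor.
#' @param mbc Metabolic demand multiplier (scalar, or a function(t_s) for
#'   scheduled changes).
#' @param duration_s Simulated duration in seconds.
#' @param stim Optional numeric vector of per-step stimulation ratios
#'   (recycled), default 0.
#' @param dynamic_rr Apply the breath-by-breath CO2 correction.
#' @param st Optional initial state.
#' @return List with `time_s`, `volume`, `co2`, `native`, `activation`
#'   traces (per step), the final `state`, and `records` (breath records
#'   from [segment_breaths()]).
#' @export
run_plant <- function(p, wi = 1, mbc = 1, duration_s = 60, stim = 0,
                      dynamic_rr = TRUE, st = NULL) {
  n <- round(duration_s / p$dt)
  mbc_fun <- if (is.function(mbc)) mbc else function(t) mbc
  if (is.null(st)) st <- plant_init_state(p, mbc_fun(0))
  stim <- rep_len(stim, n)
  volume <- numeric(n); co2 <- numeric(n); native <- numeric(n); act <- numeric(n)
  for (i in seq_len(n)) {
    m <- mbc_fun((i - 1) * p$dt)
    nat <- native_drive(st$phase, wi, p$insp_frac)
    a <- combine_activation(nat, stim[i])
    st <- lung_step(st, p, a)
    st <- metabolism_step(st, p, m)
    st <- phase_step(st, p, m, dynamic = dynamic_rr)
    volume[i] <- st$volume; co2[i] <- st$co2; native[i] <- nat; act[i] <- a
  }
  list(
    time_s = seq_len(n) * p$dt,
    volume = volume, co2 = co2, native = native, activation = act,
    state = st,
    records = segment_breaths(volume, p$dt)
  )
}

#' Calibrate the force scale and clearance gain to the eupneic targets
#'
#' Deterministic two-stage search: (1) secant iteration on `F_max` so the
#' non-injured plant at fixed eupneic rate produces the target tidal volume;
#' (2) `k_ex` set from the steady mean expired flow so CO2 clearance
#' balances production at the baseline CO2 amount; (3) the RR(mbc)
#' regression fitted by [calibrate_rr_regression()]. The returned parameters
#' satisfy Vt within `tol_vt` and per-breath CO2 drift within 0.5% at
#' eupnea.
#'
#' @param p Starting parameters.
#' @param tol_vt Relative tolerance on the tidal-volume target (default
#'   0.5%).
#' @param max_iter Secant iteration cap.
#' @param fit_regression Also fit `rr_reg` (default TRUE; disable for the
#'   fixed-rate unit tests).
#' @return Calibrated `plant_params` with attribute `"report"` describing
#'   the search.
#' @export
calibrate_plant <- function(p = plant_params(), tol_vt = 0.005, max_iter = 12,
                            fit_regression = TRUE) {
  measure_vt <- function(F_max) {
    q <- p; q$F_max <- F_max
    run <- run_plant(q, wi = 1, mbc = 1, duration_s = 20, dynamic_rr = FALSE)
    rec <- run$records
    if (nrow(rec) < 6) stop("calibrate_plant: too few breaths at F_max=", F_max)
    mean(utils::tail(rec$vt, 6))
  }
  # secant iteration on F_max (the quasi-static response is near-linear)
  f0 <- p$F_max; v0 <- measure_vt(f0)
  f1 <- f0 * p$vt0 / v0; v1 <- measure_vt(f1)
  it <- 2
  trace <- sprintf("F_max=%.1f Vt=%.4f; F_max=%.1f Vt=%.4f", f0, v0, f1, v1)
  while (abs(v1 - p$vt0) / p$vt0 > tol_vt / 2 && it < max_iter) {
    f2 <- f1 + (p$vt0 - v1) * (f1 - f0) / (v1 - v0)
    f0 <- f1; v0 <- v1; f1 <- f2; v1 <- measure_vt(f2)
    trace <- c(trace, sprintf("F_max=%.1f Vt=%.4f", f1, v1))
    it <- it + 1
  }
  if (abs(v1 - p$vt0) / p$vt0 > tol_vt) {
    stop("calibrate_plant: tidal-volume search did not converge:\n",
         paste(trace, collapse = "\n"))
  }
  p$F_max <- f1

  # clearance gain: exhalation empties the tidal volume in a short burst, so
  # per-breath clearance is exponential (not linear) in k_ex*Vt; calibrate
  # k_ex by secant iteration on the simulated steady breath-mean CO2 at the
  # fixed eupneic rate, targeting the baseline amount.
  measure_co2 <- function(k_ex) {
    q <- p; q$k_ex <- k_ex
    run <- run_plant(q, wi = 1, mbc = 1, duration_s = 24, dynamic_rr = FALSE)
    # mean CO2 over the last few full breaths
    mean(run$co2[run$time_s > 24 - 4 * 60 / p$rr0])
  }
  mean_exp_flow <- p$vt0 * p$rr0 / 60
  k0x <- p$mbc0 / (mean_exp_flow * p$co2_base)  # linearized starting point
  c0 <- measure_co2(k0x)
  k1x <- k0x * c0 / p$co2_base; c1 <- measure_co2(k1x)
  itk <- 2
  while (abs(c1 - p$co2_base) / p$co2_base > 1e-3 && itk < max_iter) {
    k2x <- k1x + (p$co2_base - c1) * (k1x - k0x) / (c1 - c0)
    k0x <- k1x; c0 <- c1; k1x <- k2x; c1 <- measure_co2(k2x)
    itk <- itk + 1
  }
  p$k_ex <- k1x

  if (fit_regression) {
    p$rr_reg <- calibrate_rr_regression(p)
  }
  attr(p, "report") <- list(
    F_max = p$F_max, vt = v1, k_ex = p$k_ex, rr_reg = p$rr_reg,
    iterations = it, trace = trace
  )
  p
}

#' Fit the RR(mbc) regression by simulation sweep
#'
#' For each metabolic demand multiplier in `mbc_grid`, runs the non-injured
#' plant with the breath-by-breath CO2-holding mechanism until the rate
#' settles, records the steady RR, and fits the least-squares line
#' RR = a + b*mbc through the points.
#'
#' @param p Calibrated plant parameters (F_max, k_ex fixed).
#' @param mbc_grid Multipliers to sweep.
#' @param duration_s Settling run length per point.
#' @return Numeric `c(a, b)`.
#' @export
calibrate_rr_regression <- function(p, mbc_grid = c(1, 1.085, 1.17),
                                    duration_s = 60) {
  q <- p
  q$rr_reg <- c(0, p$rr0)  # proportional prior; the CO2 integral sets the true rate
  rr_star <- vapply(mbc_grid, function(m) {
    run <- run_plant(q, wi = 1, mbc = m, duration_s = duration_s,
                     dynamic_rr = TRUE)
    rec <- run$records
    mean(utils::tail(rec$rr, 10))
  }, numeric(1))
  fit <- stats::lm(rr_star ~ mbc_grid)
  unname(stats::coef(fit))
}
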