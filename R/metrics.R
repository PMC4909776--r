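# Breath segmentation and respiratory summary statistics.
#
# All results downstream of a simulation are expressed per breath: tidal
# volume Vt (mL), period (s), respiratory rate RR = 60/period (breaths/min),
# minute ventilation Vt*RR (mL/min), and the coefficient of variation of RR
# over the trailing 10 breaths, whose 4% mark defines "constant RR".

#' Segment a lung-volume trace into breaths
#'
#' Breath boundaries are placed at volume minima, detected with hysteresis:
#' a new breath starts when the volume has risen by at least
#' `hysteresis_frac` of the running amplitude above the most recent minimum,
#' and the next minimum is armed only after the volume has fallen by the same
#' margin below the running maximum. This makes the detector robust to small
#' additive noise without a low-pass stage.
#'
#' @param volume Numeric vector, lung volume (mL), sampled uniformly.
#' @param dt Sample interval in seconds.
#' @param hysteresis_frac Fraction of the peak-to-trough amplitude used as
#'   the hysteresis margin (default 0.25).
#' @param min_amplitude Minimum peak-to-trough amplitude (mL) for a cycle to
#'   count as a breath (rejects a flat trace; default 0.05).
#' @return A data.frame of breath records: `index`, `t_start` (s), `period`
#'   (s), `rr` (breaths/min), `vt` (mL), `minute_ventilation` (mL/min),
#'   `cv_rr_10` (%, NA for the first 9 breaths). Empty for a flat trace.
#' @export
segment_breaths <- function(volume, dt, hysteresis_frac = 0.25,
                            min_amplitude = 0.05) {
  n <- length(volume)
  if (n < 3) return(empty_breaths())
  amp <- max(volume) - min(volume)
  if (!is.finite(amp) || amp < min_amplitude) return(empty_breaths())
  h <- hysteresis_frac * amp

  # state machine over samples: track candidate minimum, then require a rise
  # of h to confirm a breath start; require a fall of h below the running max
  # to re-arm minimum detection.
  starts <- integer(0)
  cur_min <- volume[1]; cur_min_i <- 1L
  cur_max <- -Inf
  armed <- TRUE  # looking for a confirmed minimum
  for (i in 2:n) {
    v <- volume[i]
    if (armed) {
      if (v < cur_min) { cur_min <- v; cur_min_i <- i }
      if (v >= cur_min + h) {       # rise confirms the minimum
        starts <- c(starts, cur_min_i)
        armed <- FALSE
        cur_max <- v
      }
    } else {
      if (v > cur_max) cur_max <- v
      if (v <= cur_max - h) {       # fall re-arms minimum detection
        armed <- TRUE
        cur_min <- v; cur_min_i <- i
      }
    }
  }
  if (length(starts) < 2) return(empty_breaths())

  k <- length(starts) - 1
  rec <- data.frame(
    index = seq_len(k),
    t_start = (starts[seq_len(k)] - 1) * dt,
    period = diff(starts) * dt
  )
  rec$rr <- 60 / rec$period
  rec$vt <- vapply(seq_len(k), function(j) {
    seg <- volume[starts[j]:(starts[j + 1] - 1)]
    max(seg) - min(seg)
  }, numeric(1))
  rec$minute_ventilation <- rec$vt * rec$rr
  rec$cv_rr_10 <- trailing_cv(rec$rr, window = 10)
  rec
}

empty_breaths <- function() {
  data.frame(index = integer(0), t_start = numeric(0), period = numeric(0),
             rr = numeric(0), vt = numeric(0),
             minute_ventilation = numeric(0), cv_rr_10 = numeric(0))
}

trailing_cv <- function(x, window = 10) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= window) {
    for (i in window:n) {
      w <- x[(i - window + 1):i]
      out[i] <- 100 * pop_sd(w) / mean(w)
    }
  }
  out
}

# population (divide-by-n) standard deviation: the CV convention pinned here
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Coefficient of variation of RR over the trailing window
#'
#' `100 * sd/mean` of the last `window` respiratory rates, using the
#' population (divide-by-n) standard deviation.
#'
#' @param records Breath records from [segment_breaths()], or a numeric
#'   vector of RR values.
#' @param window Trailing window length in breaths (default 10).
#' @return CV in percent.
#' @export
cv_rr <- function(records, window = 10) {
  rr <- if (is.data.frame(records)) records$rr else records
  if (length(rr) < window) {
    stop(sprintf("cv_rr: need at least %d breaths, have %d", window, length(rr)))
  }
  w <- rr[(length(rr) - window + 1):length(rr)]
  100 * pop_sd(w) / mean(w)
}

#' First breath at which the rhythm has stabilized
#'
#' The first breath index whose trailing-10 CV of RR is below `threshold`
#' percent and stays below it for the remainder of the run (a transient CV
#' peak before settling therefore does not count as stabilization).
#'
#' @param records Breath records from [segment_breaths()].
#' @param threshold CV threshold in percent (default 4, the constant-RR
#'   criterion).
#' @return Breath index, or `NA` if the run never stabilizes.
#' @export
stabilization_cycle <- function(records, threshold = 4) {
  cv <- records$cv_rr_10
  if (all(is.na(cv))) return(NA_integer_)
  below <- !is.na(cv) & cv < threshold
  # last index that is NOT below threshold (ignoring leading NAs)
  defined <- which(!is.na(cv))
  bad <- defined[!below[defined]]
  if (length(bad) == 0) return(records$index[defined[1]])
  last_bad <- max(bad)
  if (last_bad == max(defined)) return(NA_integer_)
  records$index[defined[defined > last_bad][1]]
}

#' Normalized averaged respiratory rate
#'
#' Ratio of the mean RR over the last 10 breaths between an injured run and
#' a non-injured reference run; 1.0 means the injured model breathes at the
#' reference rate.
#'
#' @param injured_records,reference_records Breath records.
#' @param window Trailing window (default 10 breaths).
#' @return The RR ratio.
#' @export
normalized_rr <- function(injured_records, reference_records, window = 10) {
  m <- function(rec) {
    rr <- rec$rr
    if (length(rr) < window) {
      stop(sprintf("normalized_rr: need at least %d breaths", window))
    }
    mean(rr[(length(rr) - window + 1):length(rr)])
  }
  m(injured_records) / m(reference_records)
}

#' Run summary in list (JSON-ready) form
#'
#' @param records Breath records.
#' @param window Trailing window for the summary means.
#' @return List with final mean RR, Vt, minute ventilation over the trailing
#'   window, the stabilization cycle, and the breath count.
#' @export
breath_summary <- function(records, window = 10) {
  n <- nrow(records)
  tail_idx <- max(1, n - window + 1):n
  list(
    n_breaths = n,
    rr = mean(records$rr[tail_idx]),
    vt = mean(records$vt[tail_idx]),
    minute_ventilation = mean(records$minute_ventilation[tail_idx]),
    cv_rr = if (n >= window) cv_rr(records, window) else NA_real_,
    stabilization_cycle = stabilization_cycle(records)
  )
}
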