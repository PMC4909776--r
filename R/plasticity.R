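# Simplified spike-timing-dependent plasticity.
#
# A two-sided step-function kernel: every causal pairing (pre spike
# followed by a post spike within the window) potentiates the connection by
# a_plus, every anti-causal pairing depresses it by a_minus; the strength
# is clamped to [p_min, p_max]. Updates are applied each computation step
# (during the kinetic phase slot) to the connections carrying a plastic
# tag in the rule's target set. There is no exponential decay inside the
# window: this is the minimal reading of a "simplified" STDP.
#
# Magnitudes, window and bounds are package calibration values (the rule's
# form is given; its constants are not printed).

#' STDP rule parameters
#'
#' @param a_plus Strength increment per causal (pre-then-post) pairing.
#' @param a_minus Strength decrement per anti-causal pairing.
#' @param window_steps Pairing window in computation steps (default 20 =
#'   10 ms, the activity-window length used throughout the controller).
#' @param p_min,p_max Clamp bounds on the strength.
#' @param targets Plastic tags this rule applies to (subset of
#'   `"P_f"`, `"P_a"`).
#' @return List of class `plasticity_rule`.
#' @export
plasticity_rule <- function(a_plus = 0.5, a_minus = 0.5, window_steps = 20,
                            p_min = 4000, p_max = 9000,
                            targets = c("P_f", "P_a")) {
  stopifnot(a_plus >= 0, a_minus >= 0, window_steps >= 1, p_min <= p_max)
  structure(
    list(a_plus = a_plus, a_minus = a_minus,
         window_steps = as.integer(window_steps),
         p_min = p_min, p_max = p_max, targets = targets),
    class = "plasticity_rule"
  )
}

#' Batch STDP update over a pair of spike histories
#'
#' Counts all ordered pairings in the given histories (earliest sample
#' first): `dP = a_plus * #{pre at i, post at j, 0 < j-i <= window} -
#' a_minus * #{post at i, pre at j, 0 < j-i <= window}` and returns the
#' clamped strength.
#'
#' @param P Current strength.
#' @param pre_history,post_history 0/1 vectors of equal length covering at
#'   least `window_steps` steps.
#' @param rule A [plasticity_rule()].
#' @return List `P` (updated, clamped) and `dP` (unclamped increment).
#' @export
stdp_update <- function(P, pre_history, post_history, rule) {
  n <- length(pre_history)
  stopifnot(length(post_history) == n, n >= rule$window_steps)
  pre_i <- which(pre_history != 0)
  post_i <- which(post_history != 0)
  count_pairs <- function(first, second) {
    if (!length(first) || !length(second)) return(0L)
    sum(vapply(first, function(i) {
      sum(second > i & second <= i + rule$window_steps)
    }, integer(1)))
  }
  dP <- rule$a_plus * count_pairs(pre_i, post_i) -
    rule$a_minus * count_pairs(post_i, pre_i)
  list(P = min(max(P + dP, rule$p_min), rule$p_max), dP = dP)
}

#' Online per-step STDP increment
#'
#' The step-wise form used inside the simulation loop, equivalent to the
#' batch count applied incrementally: when the post neuron spikes this
#' step, potentiate by `a_plus` times the number of pre spikes in the
#' trailing window; when the pre neuron spikes, depress by `a_minus` times
#' the number of post spikes in the window. (A coincident pre and post
#' spike on the same step contributes to neither side: the kernel is zero
#' at lag 0.)
#'
#' @param P Current strength.
#' @param pre_now,post_now This step's spike bits.
#' @param pre_window_count,post_window_count Spike counts over the
#'   trailing `window_steps` (not including this step).
#' @param rule A [plasticity_rule()].
#' @return Updated clamped strength.
#' @export
stdp_step <- function(P, pre_now, post_now,
                      pre_window_count, post_window_count, rule) {
  dP <- rule$a_plus * post_now * pre_window_count -
    rule$a_minus * pre_now * post_window_count
  min(max(P + dP, rule$p_min), rule$p_max)
}
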