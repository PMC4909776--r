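# Shared fixtures, built once per test run: the calibrated plant and a
# reference eupnea run. Calibration is deterministic, so every test sees
# the same parameters.

calibrated_plant <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_plant()
    cache
  }
})

eupnea_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_plant(calibrated_plant(), wi = 1, mbc = 1, duration_s = 60)
    }
    cache
  }
})

tail_mean <- function(x, n = 10) mean(utils::tail(x, n))
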