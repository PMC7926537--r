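# Shared fixtures, built once per test run.

default_test_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rest <- simulate_rest(120, noise = noise_model(seed = 1))
      cache <<- calibrate(compute_differential(rest), hand_count_params())
    }
    cache
  }
})

# Tiny synthetic sensor log: constant magnetometers, still accelerometer.
constant_sensor_log <- function(n = 60, fs = 52.6,
                                mag = c(100, -200, 300)) {
  log <- data.frame(t = (seq_len(n) - 1) / fs)
  for (i in 1:4) {
    log[[paste0("m", i, "x")]] <- mag[1]
    log[[paste0("m", i, "y")]] <- mag[2]
    log[[paste0("m", i, "z")]] <- mag[3]
  }
  log$ax <- 0; log$ay <- 0; log$az <- -1
  log$gx <- 0; log$gy <- 0; log$gz <- 0
  log
}
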