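# Shared, lazily computed fixtures.  Calibration of the patient model is the
# expensive step, so it runs once per test session and is reused everywhere.

.fixture_env <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.fixture_env$cal)) {
    .fixture_env$cal <- calibrate(seed = 0)
  }
  .fixture_env$cal
}

# calibrated model with the device configured from the synthetic bench grid
device_model <- function(p_act = 12, delay_s = 0.65) {
  cal <- cached_calibration()
  if (is.null(.fixture_env$bench)) {
    .fixture_env$bench <- synth_bench_data(seed = 1, noise_sd = 0.01)
    .fixture_env$fit <- fit_gain_surface(.fixture_env$bench)
  }
  m <- cal$model
  tim <- timing_lookup(p_act, 95, .fixture_env$bench)
  m$device <- device_params(p_act = p_act, dt_act = delay_s,
                            t_on = tim$t_on, t_off = tim$t_off,
                            gain_coeffs = .fixture_env$fit$coeffs)
  m
}

bench_fixture <- function() {
  device_model() # populates the cache
  .fixture_env$bench
}
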