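# Small deterministic fixtures built in code.

# A 3 x 5 pool with simple integer voltages, epoch -200..300 ms at
# 10 Hz (100 ms per sample): baseline window [-200, 0) covers the
# first two samples.
tiny_pool <- function() {
  segment_set(
    rbind(c(1, 3, 5, 7, 9),
          c(2, 2, 2, 2, 2),
          c(0, -4, 4, 0, -2)),
    fs = 10, t_start_ms = -200, subject_id = "tiny")
}

# A fast synthetic subject for property tests: 200 segments, 250 Hz.
quick_subject <- function(multiplier, signal_present = TRUE,
                          seed = NULL, n_segments = 200, fs = 250) {
  synth_subject(synthetic_spec(
    n_segments = n_segments, fs = fs, noise_multiplier = multiplier,
    signal_present = signal_present, seed = seed))
}

quick_cfg <- function(S = 50, B = 499, seed = NULL) {
  bootstrap_config(S = S, B = B, seed = seed)
}

# The zero-noise calibration is expensive and feeds two acceptance
# checks; compute it once per test run.
calibration_cache <- new.env(parent = emptyenv())
cached_calibration <- function() {
  if (is.null(calibration_cache$cal)) {
    calibration_cache$cal <- calibrate_zero_noise(
      bounds = c(5, 60), tolerance_db = 0.05, n_probe = 50,
      cfg = bootstrap_config(S = 200, B = 999), seed = 104L)
  }
  calibration_cache$cal
}
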