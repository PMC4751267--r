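#' Canonical synthetic ERP waveform
#'
#' A stylised visual evoked potential built from an 8 Hz
#' one-dimensional Gabor plus a late Gaussian:
#' `w(t) = sin(8*pi*t + pi) * G(t; 0.16, 0.04) + G(t; 0.5, 0.1)`,
#' where `G(t; mu, sigma) = exp(-(t - mu)^2 / (2 sigma^2))` is a
#' unit-peak Gaussian bump and `t` is in seconds relative to stimulus
#' onset. Every component envelope peaks at 1 (arbitrary units), the
#' Gabor's carrier and envelope placing P1/N1-like deflections around
#' 120–200 ms and the Gaussian a P3-like peak at 500 ms. The waveform
#' is negligible before stimulus onset (the envelopes are at least
#' 4 sigma away at t = 0).
#'
#' @param t Time axis in seconds relative to stimulus onset.
#' @return Waveform values (arbitrary units).
#' @export
canonical_waveform <- function(t) {
  gauss <- function(t, mu, sigma) exp(-(t - mu)^2 / (2 * sigma^2))
  sin(8 * pi * t + pi) * gauss(t, 0.16, 0.04) + gauss(t, 0.5, 0.1)
}

# n_series columns of pink noise, optionally low-pass filtered.
# Spectral synthesis: amplitude proportional to f^(-1/2) (power ~ 1/f)
# with iid uniform phases; DC and Nyquist are zero. Each realization
# is normalized to unit peak (max |x| = 1) before filtering, on the
# same arbitrary-units scale as the canonical waveform, whose
# components also peak at 1. The low-pass is zero-phase with the
# magnitude response of a 4th-order Butterworth (24 dB/octave),
# applied in the frequency domain; filtering is linear, so the
# filtered series is scaled by the same pre-filter peak.
pink_noise_matrix <- function(n_samples, fs, n_series = 1L,
                              lowpass = 30) {
  stopifnot(n_samples >= 8, fs > 0, n_series >= 1)
  n <- as.integer(n_samples)
  kmax <- ceiling(n / 2) - 1L           # positive-frequency bins
  f <- (1:kmax) * fs / n
  amp <- f^(-0.5)
  ph <- matrix(stats::runif(kmax * n_series, 0, 2 * pi), kmax, n_series)
  spec <- matrix(0 + 0i, n, n_series)
  spec[2:(kmax + 1L), ] <- amp * exp(1i * ph)
  spec[n:(n - kmax + 1L), ] <- Conj(spec[2:(kmax + 1L), , drop = FALSE])
  raw <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  peak <- apply(abs(raw), 2L, max)
  if (is.null(lowpass)) return(sweep(raw, 2L, peak, "/"))
  H <- 1 / sqrt(1 + (f / lowpass)^8)
  spec[2:(kmax + 1L), ] <- spec[2:(kmax + 1L), , drop = FALSE] * H
  spec[n:(n - kmax + 1L), ] <- Conj(spec[2:(kmax + 1L), , drop = FALSE])
  filt <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sweep(filt, 2L, peak, "/")
}

#' Generate 1/f (pink) noise
#'
#' Pink noise synthesised in the frequency domain: spectral amplitudes
#' proportional to `f^(-1/2)` (power proportional to `1/f`) with
#' independent uniform random phases. Each realization is normalized
#' to unit peak (`max(abs(x)) == 1`) before filtering — the same
#' arbitrary-units convention as the canonical waveform, whose
#' components peak at 1 — then low-pass filtered with a zero-phase
#' filter having the magnitude response of a 4th-order Butterworth
#' (24 dB/octave) at `lowpass` Hz, mimicking the band limit of
#' conventionally filtered EEG.
#'
#' @param n_samples Number of samples (at least 8).
#' @param fs Sampling rate in Hz.
#' @param lowpass Low-pass corner frequency in Hz (default 30);
#'   `NULL` for unfiltered pink noise.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, fs, lowpass = 30, seed = NULL) {
  with_seed(seed,
            as.vector(pink_noise_matrix(n_samples, fs, 1L, lowpass)))
}

#' Specify a synthetic ERP subject
#'
#' Parameters of one simulated subject: `n_segments` epochs over
#' `epoch`, each the canonical waveform (if `signal_present`) plus an
#' independent realization of unit-SD, 30 Hz low-passed 1/f noise
#' scaled by `noise_multiplier`. Multipliers of roughly 5–35 span high
#' to low ERP quality; around 36 the expected SNR_LB crosses 0 dB.
#'
#' @param n_segments Number of segments (default 800).
#' @param fs Sampling rate in Hz (default 1000).
#' @param epoch Epoch [time_window()] (default -200 to 800 ms).
#' @param noise_multiplier Positive noise scale factor (default 20, the
#'   midpoint of the simulated range).
#' @param signal_present `FALSE` for pure-noise (signal-absent)
#'   subjects.
#' @param subject_id Label for the simulated subject.
#' @param seed Optional RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_segments = 800, fs = 1000,
                           epoch = time_window(-200, 800),
                           noise_multiplier = 20,
                           signal_present = TRUE,
                           subject_id = "synthetic", seed = NULL) {
  stopifnot(is.numeric(n_segments), n_segments >= 1,
            is.numeric(fs), fs > 0,
            is.numeric(noise_multiplier), noise_multiplier > 0,
            is.logical(signal_present))
  epoch <- as_time_window(epoch)
  structure(list(n_segments = as.integer(n_segments), fs = fs,
                 epoch = epoch, noise_multiplier = noise_multiplier,
                 signal_present = signal_present,
                 subject_id = subject_id, seed = seed),
            class = "synthetic_spec")
}

#' Generate one synthetic ERP subject
#'
#' Builds the subject's segment pool from a [synthetic_spec()]: each
#' segment is the canonical waveform (or zero, for signal-absent
#' subjects) plus `noise_multiplier` times an independent realization
#' of normalized, 30 Hz low-passed 1/f noise. The generating `spec` is
#' recorded in the pool's provenance.
#'
#' @param spec A [synthetic_spec()].
#' @return A [segment_set()].
#' @export
synth_subject <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- round((spec$epoch$end_ms - spec$epoch$start_ms) / 1000 * spec$fs)
  t_axis <- (spec$epoch$start_ms + (seq_len(n) - 1L) * 1000 / spec$fs) / 1000
  w <- if (spec$signal_present) canonical_waveform(t_axis) else
    numeric(n)
  data <- with_seed(spec$seed, {
    noise <- pink_noise_matrix(n, spec$fs, spec$n_segments, lowpass = 30)
    t(spec$noise_multiplier * noise + w)
  })
  segment_set(
    data, fs = spec$fs, t_start_ms = spec$epoch$start_ms,
    subject_id = spec$subject_id,
    provenance = list(
      synthetic = TRUE, noise_multiplier = spec$noise_multiplier,
      signal_present = spec$signal_present, seed = spec$seed,
      noise_model = "1/f spectral synthesis, unit SD, zero-phase 30 Hz lowpass (24 dB/octave)"))
}
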