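#' Synthesise a verbal-response audio clip
#'
#' Gaussian background noise plus an amplitude-scaled voiced burst whose
#' spectral energy lies inside the 500-4000 Hz analysis band. The burst starts
#' at `latency_s` with a short raised-cosine rise (<= 10 ms), sustains with a
#' slow loudness modulation, and decays smoothly; the waveform peak of the
#' burst equals `amplitude` exactly, so extracted envelope amplitudes of two
#' clips differing only in `amplitude` are in the same ratio.
#'
#' @param latency_s burst onset within the clip, seconds (>= 0).
#' @param amplitude peak burst amplitude, arbitrary units; 0 gives a pure
#'   noise clip flagged `no_response` in the ledger.
#' @param fs_hz sampling rate; must be >= 8000 so the 4000 Hz band edge is
#'   below Nyquist.
#' @param duration_s clip duration, seconds.
#' @param noise_sd background noise SD.
#' @param seed integer seed for the noise.
#' @param burst_duration_s duration of the voiced burst.
#' @param rise_time_s onset rise time (must be <= 10 ms).
#' @param t0_rel_release_s time of the first sample relative to ball release.
#' @return An object of class `speech_clip`: list with `samples`, `fs_hz`,
#'   `t0_rel_release_s`, and a `ledger` holding the true onset (both within
#'   the clip and relative to release), the amplitude, and a `no_response`
#'   flag.
#' @examples
#' clip <- simulate_speech_clip(latency_s = 0.4, amplitude = 1, fs_hz = 16000)
#' @export
simulate_speech_clip <- function(latency_s, amplitude, fs_hz = 16000,
                                 duration_s = 1.5, noise_sd = 0.005,
                                 seed = 1L, burst_duration_s = 0.35,
                                 rise_time_s = 0.003,
                                 t0_rel_release_s = 0) {
  if (fs_hz < 8000) {
    stop("configuration error: fs_hz must be >= 8000 (band edge 4000 Hz)",
         call. = FALSE)
  }
  if (latency_s < 0 || amplitude < 0 || noise_sd < 0) {
    stop("configuration error: latency_s, amplitude and noise_sd must be >= 0",
         call. = FALSE)
  }
  if (rise_time_s > 0.010) {
    stop("configuration error: rise_time_s must be <= 10 ms", call. = FALSE)
  }
  if (latency_s + burst_duration_s >= duration_s) {
    stop("configuration error: burst must end before the clip does",
         call. = FALSE)
  }
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  set.seed(as.integer(seed))
  x <- stats::rnorm(n, 0, noise_sd)

  if (amplitude > 0) {
    in_burst <- t >= latency_s & t < latency_s + burst_duration_s
    tau <- t[in_burst] - latency_s
    env <- rep(1, length(tau))
    rise <- tau < rise_time_s
    env[rise] <- 0.5 * (1 - cos(pi * tau[rise] / rise_time_s))
    decay_t <- 0.05
    dec <- tau > burst_duration_s - decay_t
    env[dec] <- env[dec] *
      0.5 * (1 + cos(pi * (tau[dec] - (burst_duration_s - decay_t)) / decay_t))
    # mild syllable-rate loudness modulation, stays within the band
    env <- env * (1 - 0.04 * (1 + sin(2 * pi * 6 * tau)))
    carrier <- 0.5 * sin(2 * pi * 700 * tau) +
      0.3 * sin(2 * pi * 1300 * tau + 1.0) +
      0.2 * sin(2 * pi * 2400 * tau + 2.0) +
      0.15 * sin(2 * pi * 3300 * tau + 0.5)
    burst <- env * carrier
    burst <- burst * (amplitude / max(abs(burst)))
    x[in_burst] <- x[in_burst] + burst
  }

  structure(list(
    samples = x, fs_hz = fs_hz, t0_rel_release_s = t0_rel_release_s,
    ledger = list(
      onset_in_clip_s = if (amplitude > 0) latency_s else NA_real_,
      onset_rel_release_s = if (amplitude > 0) t0_rel_release_s + latency_s
                            else NA_real_,
      amplitude = amplitude,
      no_response = amplitude == 0
    )
  ), class = "speech_clip")
}

#' @export
print.speech_clip <- function(x, ...) {
  cat(sprintf("speech_clip: %.3f s at %d Hz, %s\n",
              length(x$samples) / x$fs_hz, as.integer(x$fs_hz),
              if (x$ledger$no_response) "no response (noise only)"
              else sprintf("onset %.3f s, amplitude %.3g",
                           x$ledger$onset_in_clip_s, x$ledger$amplitude)))
  invisible(x)
}
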