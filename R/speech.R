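#' Preprocess a verbal-response waveform into an amplitude envelope
#'
#' Band-pass filters the signal with a second-order Butterworth filter
#' (500-4000 Hz), offset-corrects (subtracts the mean), rectifies (absolute
#' value), and smooths with a 25 ms moving average. The output has the same
#' length as the input.
#'
#' The moving average is trailing (causal) by default, matching the causal
#' filter; a centred window leaks burst energy half a window ahead of the true
#' onset and biases the 5%-of-maximum onset rule early by ~10 ms, so the
#' causal alignment is the default and `ma_align = "center"` is an option.
#' `zero_phase = TRUE` switches the band-pass to forward-backward filtering.
#'
#' @param x numeric waveform, or a `speech_clip` (then `fs_hz` is taken from
#'   the clip).
#' @param fs_hz sampling rate; must exceed 8000 so the 4000 Hz band edge is
#'   below Nyquist.
#' @param band band-pass edges in Hz.
#' @param ma_window_s moving-average window, seconds (default 25 ms).
#' @param ma_align `"causal"` (trailing window, default) or `"center"`.
#' @param zero_phase apply the Butterworth filter forward-backward.
#' @return numeric envelope, same length as the input.
#' @examples
#' clip <- simulate_speech_clip(0.3, 1, fs_hz = 16000, duration_s = 1)
#' env <- speech_envelope(clip)
#' @export
speech_envelope <- function(x, fs_hz = NULL, band = c(500, 4000),
                            ma_window_s = 0.025,
                            ma_align = c("causal", "center"),
                            zero_phase = FALSE) {
  if (inherits(x, "speech_clip")) {
    fs_hz <- x$fs_hz
    x <- x$samples
  }
  if (is.null(fs_hz)) stop("fs_hz is required", call. = FALSE)
  if (fs_hz <= 2 * band[2]) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge",
                 fs_hz, band[2]), call. = FALSE)
  }
  ma_align <- match.arg(ma_align)
  if (!all(is.finite(x))) stop("waveform contains non-finite samples", call. = FALSE)

  bf <- signal::butter(2, band / (fs_hz / 2), type = "pass")
  filt <- if (zero_phase) signal::filtfilt(bf, x)
          else as.numeric(signal::filter(bf, x))
  filt <- filt - mean(filt)
  r <- abs(filt)

  w <- round(ma_window_s * fs_hz)
  if (w %% 2 == 0) w <- w + 1L            # odd window, exact centring
  n <- length(r)
  cs <- cumsum(r)
  if (ma_align == "causal") {
    # trailing window, shrinking at the start
    lo <- pmax(0L, seq_len(n) - w)
    (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
  } else {
    h <- (w - 1L) %/% 2L
    lo <- pmax(0L, seq_len(n) - h - 1L)
    hi <- pmin(n, seq_len(n) + h)
    (cs[hi] - c(0, cs)[lo + 1L]) / (hi - lo)
  }
}

#' Extract onset latency and maximum amplitude from an envelope
#'
#' The global envelope maximum (first occurrence on ties) is the maximal
#' amplitude; the last sample before the maximum with a value strictly below
#' 5% of the maximum marks the response onset. The clip is declared invalid
#' ("no response") when the maximum does not exceed `noise_floor_factor` times
#' the median envelope of the clip's first `noise_floor_window_s`, and
#' ("onset undetectable") when no sample before the maximum falls below the
#' 5% threshold.
#'
#' @param envelope numeric envelope from [speech_envelope()].
#' @param fs_hz sampling rate of the envelope.
#' @param t0_rel_release_s time of the first sample relative to ball release,
#'   seconds.
#' @param onset_fraction onset threshold as a fraction of the maximum.
#' @param noise_floor_window_s initial window used to estimate the noise floor.
#' @param noise_floor_factor validity requires `max > factor * noise floor`.
#' @return An object of class `speech_features`: list with `onset_latency_s`
#'   (relative to release), `max_amplitude`, `valid`, and `reason` when
#'   invalid.
#' @export
extract_features <- function(envelope, fs_hz, t0_rel_release_s = 0,
                             onset_fraction = 0.05,
                             noise_floor_window_s = 0.1,
                             noise_floor_factor = 5) {
  n <- length(envelope)
  if (n < 2 || !all(is.finite(envelope))) {
    stop("envelope must be finite and non-degenerate", call. = FALSE)
  }
  out <- function(lat, amp, valid, reason = NA_character_) {
    structure(list(onset_latency_s = lat, max_amplitude = amp,
                   valid = valid, reason = reason),
              class = "speech_features")
  }
  imax <- which.max(envelope)             # first occurrence on ties
  vmax <- envelope[imax]
  floor_n <- max(1L, min(n, round(noise_floor_window_s * fs_hz)))
  noise_floor <- stats::median(envelope[seq_len(floor_n)])
  if (!(vmax > noise_floor_factor * noise_floor)) {
    return(out(NA_real_, NA_real_, FALSE, "no response"))
  }
  below <- which(envelope[seq_len(imax - 1L)] < onset_fraction * vmax)
  if (length(below) == 0) {
    return(out(NA_real_, vmax, FALSE, "onset undetectable"))
  }
  onset_idx <- below[length(below)]
  out(t0_rel_release_s + (onset_idx - 1L) / fs_hz, vmax, TRUE)
}

#' @export
print.speech_features <- function(x, ...) {
  if (isTRUE(x$valid)) {
    cat(sprintf("speech_features: onset %.4f s rel. release, max amplitude %.4g\n",
                x$onset_latency_s, x$max_amplitude))
  } else {
    cat(sprintf("speech_features: invalid (%s)\n", x$reason))
  }
  invisible(x)
}

#' Full speech chain on a clip: envelope then feature extraction
#'
#' @param clip a `speech_clip` or numeric waveform.
#' @param fs_hz required when `clip` is a bare waveform.
#' @param t0_rel_release_s start of the clip relative to release (taken from
#'   the clip when available).
#' @param ... passed to [speech_envelope()] and [extract_features()].
#' @return `speech_features`.
#' @export
speech_features <- function(clip, fs_hz = NULL, t0_rel_release_s = NULL, ...) {
  dots <- list(...)
  if (inherits(clip, "speech_clip")) {
    fs_hz <- clip$fs_hz
    if (is.null(t0_rel_release_s)) t0_rel_release_s <- clip$t0_rel_release_s
  }
  if (is.null(t0_rel_release_s)) t0_rel_release_s <- 0
  env_args <- dots[names(dots) %in% c("band", "ma_window_s", "ma_align", "zero_phase")]
  ext_args <- dots[names(dots) %in% c("onset_fraction", "noise_floor_window_s",
                                      "noise_floor_factor")]
  env <- do.call(speech_envelope, c(list(clip, fs_hz = fs_hz), env_args))
  do.call(extract_features,
          c(list(env, fs_hz = fs_hz, t0_rel_release_s = t0_rel_release_s),
            ext_args))
}

#' Normalize speech features by the participant median
#'
#' Divides each trial's onset latency and maximum amplitude by the
#' participant's median over valid trials, yielding the dimensionless
#' `rel_latency` and `rel_amplitude` (participant median 1 by construction).
#' Participants with fewer than two valid trials are flagged and excluded
#' from speech analyses (`rel_*` set to `NA`).
#'
#' @param features data frame with columns `participant_id`,
#'   `onset_latency_s`, `max_amplitude`, `valid`.
#' @return the input with added columns `rel_latency`, `rel_amplitude`, and
#'   `participant_speech_ok`.
#' @export
normalize_by_participant <- function(features) {
  need <- c("participant_id", "onset_latency_s", "max_amplitude", "valid")
  if (!all(need %in% names(features))) {
    stop("features must contain: ", paste(need, collapse = ", "), call. = FALSE)
  }
  features$rel_latency <- NA_real_
  features$rel_amplitude <- NA_real_
  features$participant_speech_ok <- FALSE
  for (pid in unique(features$participant_id)) {
    rows <- features$participant_id == pid
    ok <- rows & features$valid %in% TRUE
    if (sum(ok) < 2) next
    med_lat <- stats::median(features$onset_latency_s[ok])
    med_amp <- stats::median(features$max_amplitude[ok])
    if (!is.finite(med_lat) || med_lat <= 0 ||
        !is.finite(med_amp) || med_amp <= 0) next
    features$rel_latency[ok] <- features$onset_latency_s[ok] / med_lat
    features$rel_amplitude[ok] <- features$max_amplitude[ok] / med_amp
    features$participant_speech_ok[rows] <- TRUE
  }
  features
}
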