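#' Ball centre from the pole markers
#'
#' The ball centre is the arithmetic midpoint of the two pole markers placed
#' on the ball's medial-lateral axis. Frames where either pole marker is
#' missing (non-finite) yield `NA` rows; event detection refuses streams with
#' flagged frames inside its search window.
#'
#' @param stream a `kinematic_stream` (see [simulate_throw_kinematics()] or
#'   [read_kinematics_csv()]).
#' @return `n x 3` matrix of ball-centre positions in metres.
#' @export
ball_center <- function(stream) {
  stopifnot(inherits(stream, "kinematic_stream"))
  pl <- stream$markers$pole_left
  pr <- stream$markers$pole_right
  if (is.null(pl) || is.null(pr)) {
    stop("stream lacks pole markers; cannot compute ball centre", call. = FALSE)
  }
  (pl + pr) / 2
}

# Per-frame invalid flags: declared flags plus frames with non-finite markers.
stream_invalid_frames <- function(stream) {
  bad <- stream$flags %||% rep(FALSE, stream$n_frames)
  for (m in stream$markers) bad <- bad | !apply(is.finite(m), 1, all)
  bad
}

# Ball speed as the norm of the central-difference velocity of the centre;
# one-sided differences at the stream ends.
ball_speed <- function(center, fs_hz) {
  n <- nrow(center)
  v <- matrix(NA_real_, n, 3)
  if (n >= 3) v[2:(n - 1), ] <- (center[3:n, ] - center[1:(n - 2), ]) * fs_hz / 2
  v[1, ] <- (center[2, ] - center[1, ]) * fs_hz
  v[n, ] <- (center[n, ] - center[n - 1, ]) * fs_hz
  sqrt(rowSums(v^2))
}

# First frame (R index) of the longest contact run strictly before R index
# `idx`; ties broken toward the later run. NA if no contact before idx.
contact_onset_before <- function(contact, idx) {
  if (idx <= 1) return(NA_integer_)
  cm <- contact[seq_len(idx - 1)]
  cm[is.na(cm)] <- FALSE
  if (!any(cm)) return(NA_integer_)
  r <- rle(cm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs] + seq_along(r$lengths)[runs] * 1e-9)]
  starts[best]
}

release_event <- function(frame, fs_hz, method, ball_speed_mps,
                          contact_duration_s) {
  structure(list(frame = as.integer(frame), time_s = frame / fs_hz,
                 method = method, confirmed = TRUE,
                 ball_speed_mps = ball_speed_mps,
                 contact_duration_s = contact_duration_s),
            class = "release_event")
}

#' @export
print.release_event <- function(x, ...) {
  cat(sprintf(
    "release_event: frame %d (%.4f s), method = %s, speed %.2f m/s, contact %.2f s\n",
    x$frame, x$time_s, x$method, x$ball_speed_mps, x$contact_duration_s))
  invisible(x)
}

#' Detect ball release from the fingertip-ball separation
#'
#' Returns the first frame at which the fingertip-to-ball-centre distance
#' increases by strictly more than `threshold_m` (default 3 mm) from one frame
#' to the next and the confirmation predicate holds: ball speed above
#' `speed_min_mps` (default 5 m/s) at that frame and more than `contact_min_s`
#' (default 0.5 s) elapsed since ball-contact onset. Contact is defined as
#' distance at most `min_dist_m + contact_tol_m`; contact onset is the first
#' frame of the longest contact run preceding the candidate.
#'
#' @param stream a `kinematic_stream`.
#' @param min_dist_m the participant's calibrated fingertip-centre distance at
#'   rest on the ball, metres.
#' @param threshold_m frame-to-frame distance increase that signals release.
#' @param speed_min_mps,contact_min_s confirmation criteria.
#' @param contact_tol_m tolerance added to `min_dist_m` for the contact epoch.
#' @return A `release_event` (frame is 0-based; `time_s = frame / fs_hz`).
#' @section Errors: `"no contact"` when no contact epoch exists;
#'   `"no release detected"` when no frame qualifies (with reason
#'   `confirmation failed` when candidates existed); streams with flagged or
#'   missing frames inside `[contact onset - 0.5 s, candidate + 5 frames]` are
#'   rejected.
#' @export
detect_release_distance <- function(stream, min_dist_m, threshold_m = 0.003,
                                    speed_min_mps = 5, contact_min_s = 0.5,
                                    contact_tol_m = 0.005) {
  stopifnot(inherits(stream, "kinematic_stream"))
  check_positive(min_dist_m, "min_dist_m")
  fs <- stream$fs_hz
  center <- ball_center(stream)
  finger <- stream$markers$fingertip
  if (is.null(finger)) stop("stream lacks a fingertip marker", call. = FALSE)
  d <- sqrt(rowSums((finger - center)^2))
  n <- length(d)
  bad <- stream_invalid_frames(stream)

  contact <- d <= min_dist_m + contact_tol_m
  if (!any(contact, na.rm = TRUE)) stop("no contact", call. = FALSE)

  dd <- c(NA_real_, diff(d))
  cand <- which(dd > threshold_m)
  if (length(cand) == 0) stop("no release detected", call. = FALSE)

  spd <- ball_speed(center, fs)
  for (idx in cand) {
    onset <- contact_onset_before(contact, idx)
    if (is.na(onset)) next
    win <- max(1L, onset - round(contact_min_s * fs)):min(n, idx + 5L)
    if (any(bad[win])) {
      stop("flagged or missing frames inside the release search window",
           call. = FALSE)
    }
    dur <- (idx - onset) / fs
    if (isTRUE(spd[idx] > speed_min_mps) && dur > contact_min_s) {
      return(release_event(idx - 1L, fs, "distance", spd[idx], dur))
    }
  }
  stop("no release detected (confirmation failed)", call. = FALSE)
}

#' Calibrate the anticipatory ball-height criterion from warm-up throws
#'
#' For each warm-up stream, locates release with the distance criterion and
#' reads the ball-centre height at the frame nearest 40 ms before release
#' (at 240 Hz, 40 ms is 9.6 frames; the nearest-frame rule reads release minus
#' 10 frames). Returns the mean height across throws -- the participant's
#' individual criterion used to trigger occlusion before actual release.
#'
#' @param warmup_streams list of at least 10 `kinematic_stream`s.
#' @param min_dist_m calibrated contact distance passed to the detector.
#' @param anticipation_s how far before release the height is read (default
#'   0.040 s).
#' @param ... further arguments for [detect_release_distance()].
#' @return criterion height in metres (scalar).
#' @export
calibrate_height_criterion <- function(warmup_streams, min_dist_m,
                                       anticipation_s = 0.040, ...) {
  heights <- rep(NA_real_, length(warmup_streams))
  fails <- character(0)
  for (i in seq_along(warmup_streams)) {
    st <- warmup_streams[[i]]
    ev <- tryCatch(detect_release_distance(st, min_dist_m, ...),
                   error = function(e) e)
    if (inherits(ev, "error")) {
      fails <- c(fails, sprintf("stream %d: %s", i, conditionMessage(ev)))
      next
    }
    idx <- ev$frame + 1L - round(anticipation_s * st$fs_hz)
    if (idx < 1) {
      fails <- c(fails, sprintf("stream %d: release too early for calibration", i))
      next
    }
    heights[i] <- ball_center(st)[idx, 3]
  }
  usable <- sum(!is.na(heights))
  if (usable < 10) {
    stop(sprintf("calibration error: only %d usable warm-ups (need 10)%s",
                 usable,
                 if (length(fails)) paste0("; ", paste(fails, collapse = "; "))
                 else ""),
         call. = FALSE)
  }
  mean(heights, na.rm = TRUE)
}

#' Detect release anticipatorily from the calibrated ball height
#'
#' Returns the first frame at which the ball-centre height crosses the
#' calibrated criterion upward and the confirmation predicate holds: contact
#' for more than `contact_min_s` up to the candidate, and ball speed exceeding
#' `speed_min_mps` within `confirm_window_frames` frames at or after the
#' candidate (the speed criterion is reached only at release itself, about
#' 40 ms later, which is the point of the anticipatory trigger).
#'
#' @inheritParams detect_release_distance
#' @param height_criterion_m criterion from [calibrate_height_criterion()].
#' @param confirm_window_frames forward window (frames) in which ball speed
#'   must exceed `speed_min_mps`.
#' @return A `release_event` with `method = "anticipatory_height"`.
#' @export
detect_release_anticipatory <- function(stream, height_criterion_m, min_dist_m,
                                        speed_min_mps = 5, contact_min_s = 0.5,
                                        confirm_window_frames = 25,
                                        contact_tol_m = 0.005) {
  stopifnot(inherits(stream, "kinematic_stream"))
  fs <- stream$fs_hz
  center <- ball_center(stream)
  finger <- stream$markers$fingertip
  d <- sqrt(rowSums((finger - center)^2))
  z <- center[, 3]
  n <- length(z)
  bad <- stream_invalid_frames(stream)
  contact <- d <= min_dist_m + contact_tol_m

  cross <- which(z[-1] >= height_criterion_m & z[-n] < height_criterion_m) + 1L
  if (length(cross) == 0) stop("no release detected", call. = FALSE)

  spd <- ball_speed(center, fs)
  for (idx in cross) {
    onset <- contact_onset_before(contact, idx + 1L)  # contact may include idx
    if (is.na(onset)) next
    win <- max(1L, onset - round(contact_min_s * fs)):min(n, idx + 5L)
    if (any(bad[win])) {
      stop("flagged or missing frames inside the release search window",
           call. = FALSE)
    }
    dur <- (idx - onset) / fs
    fwd <- idx:min(n, idx + confirm_window_frames)
    if (dur > contact_min_s && isTRUE(max(spd[fwd], na.rm = TRUE) > speed_min_mps)) {
      return(release_event(idx - 1L, fs, "anticipatory_height",
                           max(spd[fwd], na.rm = TRUE), dur))
    }
  }
  stop("no release detected (confirmation failed)", call. = FALSE)
}

#' Occlusion window following a confirmed release
#'
#' Vision is occluded for `duration_s` (default 2.5 s) from the moment of the
#' triggering release event.
#'
#' @param event a confirmed `release_event`.
#' @param duration_s occlusion duration, seconds.
#' @return named numeric `c(t_start, t_end)` in seconds.
#' @export
occlusion_window <- function(event, duration_s = 2.5) {
  if (!inherits(event, "release_event") || !isTRUE(event$confirmed)) {
    stop("occlusion_window requires a confirmed release event", call. = FALSE)
  }
  check_positive(duration_s, "duration_s")
  c(t_start = event$time_s, t_end = event$time_s + duration_s)
}
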