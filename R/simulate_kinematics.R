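#' Synthesise marker trajectories for one throw
#'
#' Builds a motion-capture stream of the five markers the release detectors
#' use (two ball "pole" markers whose midpoint is the ball centre, two
#' auxiliary triangle markers, and the fingertip of the throwing hand) with a
#' known release frame. The fingertip rides on the ball surface at
#' `min_dist_m` from the centre through a hold phase and an accelerating
#' upswing, and the ball leaves the hand between frames `release_frame - 1`
#' and `release_frame`: the first frame-to-frame increase of the
#' fingertip-centre distance (about `release_speed_mps / mocap_fs_hz`, well
#' above the 3 mm detection threshold) occurs at exactly `release_frame`.
#'
#' The upswing uses a quartic speed profile \eqn{v(s) = v_0 s^4} so ball speed
#' crosses 5 m/s only within ~3 frames of release, ball height rises
#' monotonically through the 40 ms pre-release window, and contact lasts
#' `hold_s + upswing_s` (> 0.5 s) before release. Sub-millimetre marker jitter
#' is added; the pole markers are placed symmetrically about the jittered
#' centre so the ledger centre equals the pole midpoint exactly.
#'
#' @param release_frame 0-based frame of release.
#' @param mocap_fs_hz sampling rate, frames per second.
#' @param min_dist_m fingertip-to-ball-centre distance during contact, metres
#'   (the participant's calibrated minimal distance).
#' @param n_frames total stream length; a value `<= release_frame` yields a
#'   stream truncated before release (detectors then report no release).
#' @param seed integer seed for marker jitter.
#' @param hold_height_m ball-centre height during the hold phase, metres.
#' @param release_speed_mps ball speed at release; values below 5 m/s produce
#'   throws that fail the speed confirmation.
#' @param upswing_s duration of the accelerating upswing, seconds.
#' @param hold_s duration of the static hold before the upswing, seconds.
#' @param jitter_sd_m marker jitter SD, metres.
#' @return An object of class `kinematic_stream`: list with `fs_hz`,
#'   `n_frames`, `markers` (named list of `n x 3` matrices: `pole_left`,
#'   `pole_right`, `tri_a`, `tri_b`, `fingertip`), `flags` (per-frame invalid
#'   flags), and a ground-truth `ledger` (release frame/time, ball height at
#'   the frame nearest 40 ms before release, contact onset, the true centre
#'   trajectory, and the generating parameters).
#' @examples
#' st <- simulate_throw_kinematics(release_frame = 600)
#' @export
simulate_throw_kinematics <- function(release_frame = 600, mocap_fs_hz = 240,
                                      min_dist_m = 0.12,
                                      n_frames = release_frame + 121,
                                      seed = 1L,
                                      hold_height_m = 1.8,
                                      release_speed_mps = 5.5,
                                      upswing_s = 0.3, hold_s = 0.6,
                                      jitter_sd_m = 1.5e-4) {
  check_positive(min_dist_m, "min_dist_m")
  check_positive(mocap_fs_hz, "mocap_fs_hz")
  fs <- mocap_fs_hz
  k0 <- as.integer(release_frame)
  n_up <- round(upswing_s * fs)
  pre_frames <- round((hold_s + upswing_s) * fs)
  if (k0 < pre_frames + 2) {
    stop(sprintf(
      "infeasible parameters: release_frame %d leaves no room for %.2f s of contact",
      k0, hold_s + upswing_s), call. = FALSE)
  }
  if (n_frames < 10) {
    stop("infeasible parameters: n_frames too small", call. = FALSE)
  }

  frames <- 0:(n_frames - 1)
  z <- rep(hold_height_m, n_frames)
  k_up0 <- k0 - n_up                     # first upswing frame
  t_up <- (n_up - 1) / fs                # upswing spans frames k_up0 .. k0-1

  up_idx <- frames >= k_up0 & frames <= (k0 - 1)
  s <- (frames[up_idx] - k_up0) / (n_up - 1)
  z[up_idx] <- hold_height_m + release_speed_mps * t_up * s^5 / 5

  z_rel <- hold_height_m + release_speed_mps * t_up / 5
  post_idx <- frames >= k0
  if (any(post_idx)) {
    tau <- (frames[post_idx] - (k0 - 1)) / fs
    z[post_idx] <- z_rel + release_speed_mps * tau - 0.5 * 9.81 * tau^2
  }
  center_true <- cbind(x = 0, y = 0, z = z)

  # fingertip: on the ball surface until release, then the hand stays behind
  fz <- z - min_dist_m
  if (any(post_idx)) fz[post_idx] <- z_rel - min_dist_m
  finger_true <- cbind(x = 0, y = 0, z = fz)

  set.seed(as.integer(seed))
  jit <- function() matrix(stats::rnorm(3L * n_frames, 0, jitter_sd_m),
                           ncol = 3)
  center <- center_true + jit()
  offset_pole <- c(0, 0.121, 0)
  markers <- list(
    pole_left  = sweep(center, 2, offset_pole, `-`),
    pole_right = sweep(center, 2, offset_pole, `+`),
    tri_a = sweep(center, 2, c(0.10, 0.04, 0.03), `+`) + jit(),
    tri_b = sweep(center, 2, c(0.13, -0.03, 0.06), `+`) + jit(),
    fingertip = finger_true + jit()
  )
  colnames(markers$pole_left) <- colnames(markers$pole_right) <- c("x", "y", "z")

  off40 <- round(0.040 * fs)
  h40_frame <- k0 - off40
  ledger <- list(
    release_frame = k0,
    release_time_s = k0 / fs,
    released = k0 <= n_frames - 1,
    height_40ms_pre_m = if (h40_frame >= 0 && h40_frame < n_frames)
      z[h40_frame + 1] else NA_real_,
    contact_onset_frame = 0L,
    release_speed_mps = release_speed_mps,
    min_dist_m = min_dist_m,
    center = center
  )
  structure(list(fs_hz = fs, n_frames = n_frames, markers = markers,
                 flags = rep(FALSE, n_frames), ledger = ledger),
            class = "kinematic_stream")
}

#' @export
print.kinematic_stream <- function(x, ...) {
  cat(sprintf("kinematic_stream: %d frames at %g Hz (%.2f s), markers: %s\n",
              x$n_frames, x$fs_hz, x$n_frames / x$fs_hz,
              paste(names(x$markers), collapse = ", ")))
  if (!is.null(x$ledger)) {
    cat(sprintf("  ground-truth release at frame %d (%.3f s)%s\n",
                x$ledger$release_frame, x$ledger$release_time_s,
                if (isTRUE(x$ledger$released)) "" else " [beyond stream]"))
  }
  invisible(x)
}

#' Apply a rigid transform to a kinematic stream
#'
#' Rotates all markers about the vertical axis and translates them. Used to
#' check that the release detectors are invariant to the capture-volume
#' coordinate frame.
#'
#' @param stream a `kinematic_stream`.
#' @param yaw_rad rotation about the vertical (z) axis, radians.
#' @param translation length-3 numeric offset in metres.
#' @return the transformed stream (ledger centre transformed consistently).
#' @export
transform_stream <- function(stream, yaw_rad = 0, translation = c(0, 0, 0)) {
  stopifnot(inherits(stream, "kinematic_stream"), length(translation) == 3)
  R <- matrix(c(cos(yaw_rad), -sin(yaw_rad), 0,
                sin(yaw_rad),  cos(yaw_rad), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  tf <- function(m) sweep(m %*% t(R), 2, translation, `+`)
  stream$markers <- lapply(stream$markers, tf)
  if (!is.null(stream$ledger$center)) stream$ledger$center <- tf(stream$ledger$center)
  stream
}
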