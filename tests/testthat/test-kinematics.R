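test_that("ball centre is the pole-marker midpoint", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 1)
  ctr <- ball_center(st)
  expect_equal(ctr, (st$markers$pole_left + st$markers$pole_right) / 2)
  # generator ledger centre equals the computed centre exactly
  expect_equal(max(abs(ctr - st$ledger$center)), 0)

  # hand-built two-frame stream: explicit midpoint, coincident poles
  mk <- function(pl, pr) {
    structure(list(fs_hz = 240, n_frames = nrow(pl),
                   markers = list(pole_left = pl, pole_right = pr,
                                  fingertip = pl),
                   flags = rep(FALSE, nrow(pl)), ledger = NULL),
              class = "kinematic_stream")
  }
  s1 <- mk(matrix(c(0, 0, 2), 1), matrix(c(0.24, 0, 2), 1))
  expect_equal(drop(ball_center(s1)), c(0.12, 0, 2))
  s2 <- mk(matrix(c(1, 1, 1), 1), matrix(c(1, 1, 1), 1))
  expect_equal(drop(ball_center(s2)), c(1, 1, 1))
})

test_that("distance-criterion release is found within one frame of ground truth", {
  for (s in 1:10) {
    k0 <- sample(450:700, 1)
    st <- simulate_throw_kinematics(release_frame = k0, seed = s)
    ev <- detect_release_distance(st, min_dist_m = 0.12)
    expect_true(abs(ev$frame - k0) <= 1)
    expect_true(ev$confirmed)
    expect_gt(ev$ball_speed_mps, 5)
    expect_gt(ev$contact_duration_s, 0.5)
    expect_equal(ev$time_s, ev$frame / st$fs_hz)
  }
})

test_that("detector agrees with an exhaustive brute-force frame scan", {
  for (s in 1:5) {
    st <- simulate_throw_kinematics(release_frame = 500 + 7 * s, seed = s)
    ev <- detect_release_distance(st, min_dist_m = 0.12)
    expect_identical(ev$frame, oracle_release_scan(st, 0.12))
  }
})

test_that("sub-threshold or constant separation yields no release", {
  # constant distance: contact never broken
  st <- simulate_throw_kinematics(release_frame = 600, n_frames = 550, seed = 2)
  expect_error(detect_release_distance(st, 0.12), "no release detected")

  # distance creeping at 0.002 m/frame stays below the strict 0.003 threshold
  n <- 400
  z <- rep(1.5, n)
  ctr <- cbind(0, 0, z)
  d <- 0.12 + c(rep(0, 200), cumsum(rep(0.002, n - 200)))
  fing <- cbind(0, 0, z - d)
  st2 <- structure(list(fs_hz = 240, n_frames = n,
                        markers = list(pole_left = sweep(ctr, 2, c(0, 0.12, 0), `-`),
                                       pole_right = sweep(ctr, 2, c(0, 0.12, 0), `+`),
                                       fingertip = fing),
                        flags = rep(FALSE, n), ledger = NULL),
                   class = "kinematic_stream")
  expect_error(detect_release_distance(st2, 0.12), "no release detected")

  # no contact epoch at all
  st3 <- st2
  st3$markers$fingertip <- fing - 0.5
  expect_error(detect_release_distance(st3, 0.12), "no contact")
})

test_that("slow throws fail the speed confirmation", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 3,
                                  release_speed_mps = 3)
  expect_error(detect_release_distance(st, 0.12), "confirmation failed")
})

test_that("height calibration reads the frame nearest 40 ms before release", {
  warm <- lapply(1:10, function(s)
    simulate_throw_kinematics(release_frame = 600, seed = 100 + s))
  crit <- calibrate_height_criterion(warm, min_dist_m = 0.12)
  # 40 ms at 240 Hz is 9.6 frames -> nearest-frame rule reads release - 10
  truth <- warm[[1]]$ledger$height_40ms_pre_m
  expect_lt(abs(crit - truth), 0.002)

  # fewer than 10 usable warm-ups is a calibration error naming the failures
  warm[[3]] <- simulate_throw_kinematics(release_frame = 600, n_frames = 550,
                                         seed = 103)
  expect_error(calibrate_height_criterion(warm, 0.12), "stream 3")
})

test_that("anticipatory release precedes the distance release by about 40 ms", {
  warm <- lapply(1:10, function(s)
    simulate_throw_kinematics(release_frame = 600, seed = 200 + s))
  crit <- calibrate_height_criterion(warm, min_dist_m = 0.12)
  for (s in 1:10) {
    st <- simulate_throw_kinematics(release_frame = 580 + 5 * s,
                                    seed = 300 + s)
    ev_d <- detect_release_distance(st, 0.12)
    ev_a <- detect_release_anticipatory(st, crit, 0.12)
    gap_ms <- (ev_d$time_s - ev_a$time_s) * 1000
    expect_gt(gap_ms, 0)
    expect_lt(abs(gap_ms - 40), 8)
  }
})

test_that("anticipatory detection errors are specific", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 4)
  expect_error(detect_release_anticipatory(st, 10, 0.12),
               "no release detected")
  slow <- simulate_throw_kinematics(release_frame = 600, seed = 5,
                                    release_speed_mps = 3)
  crit_slow <- slow$ledger$height_40ms_pre_m
  expect_error(detect_release_anticipatory(slow, crit_slow, 0.12),
               "confirmation failed")
})

test_that("detection is invariant to rigid motion of the capture frame", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 6)
  ev <- detect_release_distance(st, 0.12)
  moved <- transform_stream(st, yaw_rad = 0.7, translation = c(3, -2, 0.5))
  ev2 <- detect_release_distance(moved, 0.12)
  expect_identical(ev$frame, ev2$frame)
  expect_equal(ev$ball_speed_mps, ev2$ball_speed_mps, tolerance = 1e-10)

  # anticipatory criterion uses absolute height: invariant to horizontal
  # translation and yaw
  warm <- lapply(1:10, function(s)
    simulate_throw_kinematics(release_frame = 600, seed = 400 + s))
  crit <- calibrate_height_criterion(warm, 0.12)
  flat <- transform_stream(st, yaw_rad = 1.2, translation = c(-5, 4, 0))
  expect_identical(detect_release_anticipatory(st, crit, 0.12)$frame,
                   detect_release_anticipatory(flat, crit, 0.12)$frame)
})

test_that("streams with flagged frames near the release are rejected", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 8)
  st$flags[595] <- TRUE
  expect_error(detect_release_distance(st, 0.12), "flagged")
  st2 <- simulate_throw_kinematics(release_frame = 600, seed = 8)
  st2$markers$fingertip[590, 2] <- NA
  expect_error(detect_release_distance(st2, 0.12), "flagged")
})

test_that("occlusion window spans 2.5 s from a confirmed release", {
  ev <- structure(list(frame = 480L, time_s = 2, method = "distance",
                       confirmed = TRUE, ball_speed_mps = 6,
                       contact_duration_s = 1), class = "release_event")
  expect_equal(occlusion_window(ev), c(t_start = 2, t_end = 4.5))
  expect_equal(occlusion_window(ev, duration_s = 1), c(t_start = 2, t_end = 3))
  ev$confirmed <- FALSE
  expect_error(occlusion_window(ev), "confirmed")
})

test_that("kinematics CSV round-trips through the long format", {
  st <- simulate_throw_kinematics(release_frame = 600, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_kinematics_csv(st, f)
  st2 <- read_kinematics_csv(f, fs_hz = 240)
  ev <- detect_release_distance(st2, 0.12)
  expect_true(abs(ev$frame - 600) <= 1)
  unlink(f)
})
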