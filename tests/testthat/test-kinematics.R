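test_that("segment angles recover explicit rigid rotations about the vertical axis", {
  theta <- c(0, 5, 12, 30, 30, 12, 0, -8)
  tr <- rigid_trial(theta)
  ang <- segment_angles(tr, cutoff_hz = NULL)
  # sign convention flips so the largest-magnitude thorax angle is positive;
  # here max |theta| = 30 > 0 already, so no flip
  expect_equal(ang$pelvis_deg, theta, tolerance = 1e-9)
  expect_equal(ang$thorax_deg, theta, tolerance = 1e-9)
  expect_equal(ang$pelvis_deg[1], 0, tolerance = 1e-12)  # setup zeroing
  expect_equal(ang$thorax_deg[7], 0, tolerance = 1e-9)   # +theta then -theta

  # backswing-negative raw rotation is auto-flipped to positive
  tr2 <- rigid_trial(-theta)
  ang2 <- segment_angles(tr2, cutoff_hz = NULL)
  expect_equal(ang2$thorax_deg, theta, tolerance = 1e-9)
})

test_that("degenerate segment lines are rejected", {
  tr <- rigid_trial(rep(0, 10))
  for (cc in c("LACR_x", "LACR_y")) tr[[cc]] <- tr[[sub("LACR", "RACR", cc)]]
  expect_error(segment_angles(tr, cutoff_hz = NULL), "thorax line degenerate")
})

test_that("club speed and acceleration match analytic kinematics", {
  fs <- 200; n <- 100
  # constant velocity 2 m/s along X
  tr <- rigid_trial(rep(0, n),
                    club_xyz = function(i, m) c(2 * (i - 1) / fs, 1, 0.1))
  ck <- club_speed_accel(tr, cutoff_hz = NULL)
  expect_equal(ck$speed_mps, rep(2, n), tolerance = 1e-9)
  expect_equal(ck$accel_mps2[3:(n - 2)], rep(0, n - 4), tolerance = 1e-6)

  # circular motion radius r, angular rate w: speed rw, accel rw^2
  r <- 1.3; w <- 4
  trc <- rigid_trial(rep(0, n), club_xyz = function(i, m) {
    a <- w * (i - 1) / fs
    c(r * cos(a), r * sin(a), 0.1)
  })
  ckc <- club_speed_accel(trc, cutoff_hz = NULL)
  mid <- 5:(n - 5)
  expect_equal(ckc$speed_mps[mid], rep(r * w, length(mid)), tolerance = 1e-3)
  expect_equal(ckc$accel_mps2[mid], rep(r * w^2, length(mid)), tolerance = 1e-2)

  # stationary marker: zero speed
  trs <- constant_trial(n)
  expect_equal(club_speed_accel(trs, cutoff_hz = NULL)$speed_mps,
               rep(0, n), tolerance = 1e-12)

  expect_error(club_speed_accel(constant_trial(4), cutoff_hz = NULL),
               "at least 5 frames")
})

test_that("events match generator ground truth within one frame (noiseless)", {
  profs <- list(
    swing_profile(noise_sd_m = 0),
    swing_profile(pmax_deg = 30, tmax_deg = 80, gcv_mps = 18, noise_sd_m = 0),
    swing_profile(pmax_deg = 60, tmax_deg = 130, gcv_mps = 30,
                  backswing_duration = 1.1, noise_sd_m = 0),
    swing_profile(pelvis_onset_lag = 0.04, transition_lead = 0.04,
                  noise_sd_m = 0)
  )
  for (prof in profs) {
    tr <- generate_trial(prof, seed = 1)
    gt <- ground_truth(tr)$events
    ev <- detect_events(tr, cutoff_hz = NULL)
    expect_lte(abs(ev$start_frame - gt$start_frame), 1)
    expect_lte(abs(ev$top_frame - gt$top_frame), 1)
    expect_lte(abs(ev$impact_frame - gt$impact_frame), 1)
  }
})

test_that("a motionless recording raises a no-swing error", {
  expect_error(detect_events(constant_trial(), cutoff_hz = NULL),
               "no swing detected")
})

test_that("event ordering holds across a noisy generated cohort", {
  co <- generate_cohort(2, 2, 3, seed = 17)
  for (tr in co$trials) {
    ev <- detect_events(tr)   # default filtering, 2 mm noise
    expect_true(ev$start_frame < ev$top_frame &&
                ev$top_frame < ev$impact_frame)
  }
})

test_that("event detection is invariant to a rigid translation of the lab frame", {
  tr <- generate_trial(swing_profile(), seed = 33)
  ev0 <- detect_events(tr)
  shifted <- as.data.frame(tr)
  for (m in c("x", "y", "z")) {
    off <- c(x = 1.2, y = -0.7, z = 0.3)[[m]]
    for (cc in grep(paste0("_", m, "$"), names(shifted), value = TRUE)) {
      shifted[[cc]] <- shifted[[cc]] + off
    }
  }
  tr2 <- swing_trial(shifted, "test", 1L, 200)
  ev1 <- detect_events(tr2)
  expect_identical(unclass(ev0), unclass(ev1))
})

test_that("X-factor definitions hold exactly and stretch responds to pelvis lead", {
  tr <- generate_trial(swing_profile(noise_sd_m = 0), seed = 1)
  ang <- segment_angles(tr, cutoff_hz = NULL)
  ev <- detect_events(tr, cutoff_hz = NULL)
  ck <- club_speed_accel(tr, cutoff_hz = NULL)
  pars <- extract_parameters(ang, ev, ck)
  expect_identical(pars$xfac_deg,
                   ang$thorax_deg[ev$top_frame] - ang$pelvis_deg[ev$top_frame])
  # independent re-computation of the stretch from the separation curve
  sep <- ang$thorax_deg - ang$pelvis_deg
  expect_identical(pars$sxfac_deg,
                   max(0, max(sep[ev$top_frame:ev$impact_frame]) - sep[ev$top_frame]))

  # simultaneous reversal: separation peaks at the top, stretch is zero
  tr0 <- generate_trial(swing_profile(noise_sd_m = 0, pelvis_onset_lag = 0,
                                      transition_lead = 0), seed = 1)
  a0 <- analyze_trial(tr0, cutoff_hz = NULL)
  expect_equal(a0$parameters$sxfac_deg, 0, tolerance = 1e-9)

  # pelvis reversing 40 ms early must grow the X-factor after the top
  tr40 <- generate_trial(swing_profile(noise_sd_m = 0, transition_lead = 0.04),
                         seed = 1)
  a40 <- analyze_trial(tr40, cutoff_hz = NULL)
  expect_gt(a40$parameters$sxfac_deg, 0)
  expect_error(extract_parameters(ang, structure(list(
    start_frame = 10L, top_frame = 50L, impact_frame = 50L),
    class = "swing_events"), ck), "impact must follow")
})

test_that("parameters stay stable under 2 mm marker noise", {
  prof <- swing_profile(noise_sd_m = 0.002)
  reps <- 60
  out <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    tr <- generate_trial(prof, seed = 1000 + i)
    a <- analyze_trial(tr)   # default 10 Hz zero-lag filtering
    out[i, ] <- c(a$parameters$pmax_deg, a$parameters$tmax_deg,
                  a$parameters$gcv_mps)
  }
  expect_lt(sd(out[, 1]), 1.5)   # degrees
  expect_lt(sd(out[, 2]), 1.5)
  expect_lt(sd(out[, 3]), 0.3)   # m/s
})
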