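#' Transverse-plane pelvis and thorax rotation angles
#'
#' The pelvis line runs from the right-side centroid (mean of RASIS and
#' RPSIS) to the left-side centroid, the thorax line from RACR to LACR,
#' both projected onto the horizontal x-y plane. Each series is the
#' four-quadrant angle of that line to the +X (target) axis, unwrapped,
#' offset so the setup frame reads zero, and sign-oriented so that
#' backswing rotation (away from the target) is positive — the flip is
#' decided by requiring the thorax angle at its extremum to be positive.
#'
#' @param trial a [swing_trial()].
#' @param cutoff_hz optional low-pass cutoff applied to marker positions
#'   before the angle computation; `NULL` disables filtering.
#' @param setup_frames number of initial frames averaged for the zero
#'   offset (1 = first frame).
#' @return a tibble with columns `frame`, `time`, `pelvis_deg`,
#'   `thorax_deg` and a `sample_rate` attribute.
#' @export
segment_angles <- function(trial, cutoff_hz = 10, setup_frames = 1L) {
  stopifnot(inherits(trial, "swing_trial"))
  fs <- trial_sample_rate(trial)
  g <- function(col) {
    v <- trial[[col]]
    if (!is.null(cutoff_hz)) v <- lowpass(v, cutoff_hz, fs) else v
  }
  line_angle <- function(rx, ry, lx, ly, what) {
    dx <- lx - rx
    dy <- ly - ry
    if (any(dx^2 + dy^2 < 1e-12)) {
      abort(paste0(what, " line degenerate: left/right centroids coincide"))
    }
    signal::unwrap(atan2(dy, dx)) * 180 / pi
  }
  pelvis <- line_angle((g("RASIS_x") + g("RPSIS_x")) / 2,
                       (g("RASIS_y") + g("RPSIS_y")) / 2,
                       (g("LASIS_x") + g("LPSIS_x")) / 2,
                       (g("LASIS_y") + g("LPSIS_y")) / 2, "pelvis")
  thorax <- line_angle(g("RACR_x"), g("RACR_y"),
                       g("LACR_x"), g("LACR_y"), "thorax")
  k <- max(1L, min(setup_frames, length(pelvis)))
  pelvis <- pelvis - mean(pelvis[1:k])
  thorax <- thorax - mean(thorax[1:k])
  # orient so the backswing is positive: thorax extremum must be positive
  if (thorax[which.max(abs(thorax))] < 0) {
    pelvis <- -pelvis
    thorax <- -thorax
  }
  out <- tibble(frame = trial$frame, time = trial$time,
                pelvis_deg = pelvis, thorax_deg = thorax)
  attr(out, "sample_rate") <- fs
  out
}

#' Club-head speed and acceleration magnitude
#'
#' Marker positions are optionally low-pass filtered, then differentiated
#' by central differences (one-sided at the ends). Speed is the Euclidean
#' norm of the velocity; acceleration magnitude is the norm of the
#' velocity's derivative.
#'
#' @inheritParams segment_angles
#' @return a tibble with columns `frame`, `time`, `speed_mps`,
#'   `accel_mps2`, `vx_mps` (X velocity component, used for direction
#'   gating in event detection).
#' @export
club_speed_accel <- function(trial, cutoff_hz = 10) {
  stopifnot(inherits(trial, "swing_trial"))
  if (nrow(trial) < 5) abort("need at least 5 frames to differentiate")
  fs <- trial_sample_rate(trial)
  pos <- vapply(paste0("CLUB_HEAD_", c("x", "y", "z")), function(cc) {
    v <- trial[[cc]]
    if (!is.null(cutoff_hz)) lowpass(v, cutoff_hz, fs) else v
  }, numeric(nrow(trial)))
  vel <- apply(pos, 2, deriv_central, fs = fs)
  acc <- apply(vel, 2, deriv_central, fs = fs)
  tibble(frame = trial$frame, time = trial$time,
         speed_mps = sqrt(rowSums(vel^2)),
         accel_mps2 = sqrt(rowSums(acc^2)),
         vx_mps = vel[, 1])
}

#' Detect swing start, top of backswing, and impact
#'
#' Events are defined on the club-head marker: the swing starts when its
#' speed first reaches 0.2 m/s moving away from the target (negative X
#' velocity for right-handed players with the target at +X) and stays
#' above threshold for at least `debounce_s`; the top of the backswing is
#' the speed minimum between the start and the global speed maximum;
#' impact is the acceleration-magnitude peak within `impact_window_s` of
#' the global speed maximum, after the top.
#'
#' @inheritParams segment_angles
#' @param speed_threshold swing-start speed threshold (m/s).
#' @param debounce_s duration the start speed must be sustained (s).
#' @param impact_window_s half-width of the impact search window (s).
#' @param target_direction `+1` if the target lies at +X (right-handed
#'   setup), `-1` to flip for left-handed data.
#' @return a `swing_events` list with `start_frame`, `top_frame`,
#'   `impact_frame` (1-based).
#' @export
detect_events <- function(trial, cutoff_hz = 10, speed_threshold = 0.2,
                          debounce_s = 0.05, impact_window_s = 0.05,
                          target_direction = 1) {
  ck <- club_speed_accel(trial, cutoff_hz = cutoff_hz)
  fs <- trial_sample_rate(trial)
  speed <- ck$speed_mps
  n <- length(speed)
  if (max(speed) < 1) abort("no swing detected: club speed never exceeds 1 m/s",
                            class = "golfswing_no_swing")

  g <- which.max(speed)
  k <- max(1L, round(debounce_s * fs))
  away <- target_direction * ck$vx_mps < 0
  start_frame <- NA_integer_
  for (i in seq_len(max(1L, g - k))) {
    if (speed[i] >= speed_threshold && away[i] &&
        all(speed[i:min(n, i + k)] >= speed_threshold)) {
      start_frame <- i
      break
    }
  }
  if (is.na(start_frame)) {
    abort("no swing detected: start threshold never sustained",
          class = "golfswing_no_swing")
  }
  if (g <= start_frame + 1) abort("events out of order: speed peak at/before start")

  win <- (start_frame + 1):(g - 1)
  top_frame <- win[which.min(speed[win])]
  # the speed minimum at the reversal is locally V-shaped and central
  # differences smear the sample nearest the vertex; intersecting the
  # outer slopes recovers the true frame when the raw argmin is off by one
  if (top_frame - 2 >= 1 && top_frame + 2 <= n) {
    sl <- speed[top_frame - 1] - speed[top_frame - 2]
    sr <- speed[top_frame + 2] - speed[top_frame + 1]
    if (sl < 0 && sr > 0) {
      xstar <- (speed[top_frame + 1] - speed[top_frame - 1] +
                  sl * (top_frame - 1) - sr * (top_frame + 1)) / (sl - sr)
      top_frame <- max(win[1], min(tail(win, 1),
                                   max(top_frame - 1L,
                                       min(top_frame + 1L, round(xstar)))))
    }
  }
  if (speed[top_frame] > 0.5) {
    warn(sprintf("sloppy backswing transition: minimum club speed %.2f m/s",
                 speed[top_frame]))
  }

  w <- round(impact_window_s * fs)
  iw <- max(top_frame + 1L, g - w):min(n, g + w)
  impact_frame <- iw[which.max(ck$accel_mps2[iw])]
  if (!(start_frame < top_frame && top_frame < impact_frame)) {
    abort("internal error: events out of order")
  }
  structure(list(start_frame = start_frame, top_frame = top_frame,
                 impact_frame = impact_frame),
            class = "swing_events")
}

#' @export
print.swing_events <- function(x, ...) {
  cat(sprintf("<swing_events> start %d, top %d, impact %d\n",
              x$start_frame, x$top_frame, x$impact_frame))
  invisible(x)
}

#' Extract the five discrete swing parameters
#'
#' * `pmax_deg`, `tmax_deg`: absolute pelvis / thorax rotation between the
#'   swing start and the top of the backswing;
#' * `xfac_deg`: thorax minus pelvis angle at the top (positive when the
#'   thorax has rotated further);
#' * `sxfac_deg`: how far the thorax-pelvis separation grows beyond the
#'   top-of-backswing X-factor between top and impact, floored at zero;
#' * `gcv_mps`: peak club-head speed after the top, up to and including
#'   impact.
#'
#' @param angles output of [segment_angles()].
#' @param events a `swing_events` from [detect_events()].
#' @param club output of [club_speed_accel()] on the same trial.
#' @return one-row tibble of the five parameters.
#' @export
extract_parameters <- function(angles, events, club) {
  s <- events$start_frame; p <- events$top_frame; i <- events$impact_frame
  if (i <= p) abort("impact must follow the top of the backswing")
  stopifnot(nrow(angles) == nrow(club), i <= nrow(angles))
  sep <- angles$thorax_deg - angles$pelvis_deg
  xfac <- sep[p]
  tibble(
    tmax_deg = abs(angles$thorax_deg[p] - angles$thorax_deg[s]),
    pmax_deg = abs(angles$pelvis_deg[p] - angles$pelvis_deg[s]),
    xfac_deg = xfac,
    sxfac_deg = max(0, max(sep[p:i]) - xfac),
    gcv_mps = max(club$speed_mps[(p + 1):i])
  )
}

#' Full per-trial kinematic analysis
#'
#' Convenience wrapper: angles, club kinematics, events and parameters in
#' one call, returning a single list for pipeline use.
#'
#' @inheritParams detect_events
#' @return list with `angles`, `club`, `events`, `parameters`.
#' @export
analyze_trial <- function(trial, cutoff_hz = 10, target_direction = 1) {
  angles <- segment_angles(trial, cutoff_hz = cutoff_hz)
  club <- club_speed_accel(trial, cutoff_hz = cutoff_hz)
  events <- detect_events(trial, cutoff_hz = cutoff_hz,
                          target_direction = target_direction)
  params <- extract_parameters(angles, events, club)
  list(angles = angles, club = club, events = events, parameters = params)
}
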