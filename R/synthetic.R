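# Setup marker geometry (metres, lab frame: X = target line, Z vertical).
# Pelvis markers +/-0.14 laterally, ASIS 0.12 m anterior of PSIS; acromia
# +/-0.20 m; club head 1.10 m from the grip marker. Fixed constants chosen
# once for the simulator; the analysis never assumes them.
SETUP_GEOMETRY <- list(
  LASIS = c( 0.14, -0.06, 1.00), RASIS = c(-0.14, -0.06, 1.00),
  LPSIS = c( 0.14,  0.06, 1.05), RPSIS = c(-0.14,  0.06, 1.05),
  LACR  = c( 0.20,  0.00, 1.45), RACR  = c(-0.20,  0.00, 1.45)
)
CLUB_RADII <- c(grip = 0.35, head = 1.45)   # head - grip = 1.10 m
CLUB_Z <- c(grip = 0.90, head = 0.05)
CLUB_ALPHA0 <- pi / 2      # setup azimuth: early backswing moves the head to -X
IMPACT_TAU <- 0.010        # s, exponential post-impact deceleration constant

#' Describe one synthetic swing
#'
#' Collects the kinematic parameters of a simulated stroke. Pelvis and
#' thorax rotate about the vertical axis with raised-cosine ramps
#' (0 to amplitude over the backswing, amplitude to past zero over the
#' downswing); the thorax starts first when `pelvis_onset_lag > 0` and the
#' pelvis reverses `transition_lead` seconds before the thorax, which
#' stretches the X-factor after the top. The club head follows a circular
#' arc whose speed is zero at the top, rises to `gcv_mps` exactly at
#' impact, and then collapses exponentially (the impact deceleration
#' spike used by event detection).
#'
#' @param pmax_deg,tmax_deg pelvis / thorax rotation amplitude (degrees).
#' @param gcv_mps peak club-head speed at impact (m/s).
#' @param backswing_duration,downswing_duration phase durations (s).
#' @param pelvis_onset_lag s by which the pelvis starts after the thorax.
#' @param transition_lead s before the top at which the pelvis reverses.
#' @param noise_sd_m isotropic Gaussian marker noise SD (m).
#' @param setup_hold s of stationary address posture before the swing.
#' @param follow_frac follow-through amplitude as a fraction of the
#'   backswing amplitude.
#' @param tail s recorded after impact.
#' @param sample_rate sampling rate (Hz).
#' @return a `swing_profile` list.
#' @export
swing_profile <- function(pmax_deg = 46.8, tmax_deg = 110.6, gcv_mps = 23.0,
                          backswing_duration = 0.9, downswing_duration = 0.32,
                          pelvis_onset_lag = 0, transition_lead = 0.02,
                          noise_sd_m = 0.002, setup_hold = 0.5,
                          follow_frac = 0.6, tail = 0.2, sample_rate = 200) {
  stopifnot(pmax_deg >= 0, tmax_deg >= 0, gcv_mps > 0,
            backswing_duration > 0, downswing_duration > 0,
            noise_sd_m >= 0, setup_hold > 0, tail > 0, sample_rate > 0,
            transition_lead >= 0, transition_lead < downswing_duration,
            pelvis_onset_lag >= 0, pelvis_onset_lag < backswing_duration)
  structure(as.list(environment()), class = "swing_profile")
}

# Raised-cosine segment rotation (deg): 0 until `b`, up to `A` at `p`,
# down to -follow_frac*A at `e`, held thereafter. C1 everywhere.
segment_angle_fun <- function(A, b, p, e, follow_frac) {
  F_ <- follow_frac * A
  function(t) {
    th <- numeric(length(t))
    up <- t >= b & t <= p
    th[up] <- A / 2 * (1 - cos(pi * (t[up] - b) / (p - b)))
    dn <- t > p & t <= e
    th[dn] <- A - (A + F_) / 2 * (1 - cos(pi * (t[dn] - p) / (e - p)))
    th[t > e] <- -F_
    th
  }
}

# Club azimuth (rad) and angular rate (rad/s) as functions of time.
# Backswing: raised cosine over [t0, p] with amplitude `sweep`;
# downswing: rate ramps as sin(pi/2 * s/Td) so the speed peak falls
# exactly at impact; post-impact: exponential decay of the rate.
club_alpha_fun <- function(omega_max, t0, p, e, tau) {
  td <- e - p
  sweep <- omega_max * 2 * td / pi
  list(
    alpha = function(t) {
      a <- rep(CLUB_ALPHA0, length(t))
      up <- t >= t0 & t <= p
      a[up] <- CLUB_ALPHA0 + sweep / 2 * (1 - cos(pi * (t[up] - t0) / (p - t0)))
      dn <- t > p & t <= e
      a[dn] <- CLUB_ALPHA0 + sweep -
        omega_max * 2 * td / pi * (1 - cos(pi / 2 * (t[dn] - p) / td))
      po <- t > e
      a[po] <- CLUB_ALPHA0 - omega_max * tau * (1 - exp(-(t[po] - e) / tau))
      a
    },
    rate = function(t) {
      w <- numeric(length(t))
      up <- t >= t0 & t <= p
      w[up] <- sweep / 2 * pi / (p - t0) * sin(pi * (t[up] - t0) / (p - t0))
      dn <- t > p & t <= e
      w[dn] <- omega_max * sin(pi / 2 * (t[dn] - p) / td)
      po <- t > e
      w[po] <- -omega_max * exp(-(t[po] - e) / tau)  # reversed sign = same arc direction
      w
    }
  )
}

#' Generate one synthetic trial with analytic ground truth
#'
#' Marker positions are the rigid rotation of the setup geometry about the
#' vertical axis by the profile's segment angles, plus seeded isotropic
#' Gaussian noise. The returned trial carries a `ground_truth` attribute
#' (see [ground_truth()]) holding the noiseless event frames and the swing
#' parameters evaluated on the noiseless series — the oracle for event
#' detection and parameter recovery.
#'
#' @param profile a [swing_profile()].
#' @param participant_id,trial_index identifiers for the trial.
#' @param seed integer seed; required, the generator is always reproducible.
#' @return a [swing_trial()] with attached ground truth.
#' @export
generate_trial <- function(profile, participant_id = "sim", trial_index = 1L,
                           seed) {
  stopifnot(inherits(profile, "swing_profile"))
  if (missing(seed) || is.null(seed)) abort("generate_trial requires a seed")
  fs <- profile$sample_rate

  snap <- function(x) round(x * fs) / fs
  t0 <- snap(profile$setup_hold)
  tb <- snap(profile$backswing_duration)
  td <- snap(profile$downswing_duration)
  lag <- snap(profile$pelvis_onset_lag)
  lead <- snap(profile$transition_lead)
  t_top <- t0 + tb
  t_imp <- t_top + td
  n <- round((t_imp + profile$tail) * fs) + 1L
  tt <- (seq_len(n) - 1) / fs

  thorax_fun <- segment_angle_fun(profile$tmax_deg, t0, t_top, t_imp,
                                  profile$follow_frac)
  pelvis_fun <- segment_angle_fun(profile$pmax_deg, t0 + lag, t_top - lead,
                                  t_imp, profile$follow_frac)
  omega_max <- profile$gcv_mps / CLUB_RADII[["head"]]
  club <- club_alpha_fun(omega_max, t0, t_top, t_imp, IMPACT_TAU)

  th_deg <- thorax_fun(tt)
  pe_deg <- pelvis_fun(tt)
  alpha <- club$alpha(tt)
  rate <- club$rate(tt)

  dat <- tibble(frame = seq_len(n), time = tt)
  rot <- function(p0, theta_rad) {
    cbind(p0[1] * cos(theta_rad) - p0[2] * sin(theta_rad),
          p0[1] * sin(theta_rad) + p0[2] * cos(theta_rad),
          rep(p0[3], length(theta_rad)))
  }
  for (m in names(SETUP_GEOMETRY)) {
    ang <- if (m %in% c("LACR", "RACR")) th_deg else pe_deg
    xyz <- rot(SETUP_GEOMETRY[[m]], ang * pi / 180)
    dat[[paste0(m, "_x")]] <- xyz[, 1]
    dat[[paste0(m, "_y")]] <- xyz[, 2]
    dat[[paste0(m, "_z")]] <- xyz[, 3]
  }
  for (m in c("CLUB_GRIP", "CLUB_HEAD")) {
    r <- CLUB_RADII[[if (m == "CLUB_GRIP") "grip" else "head"]]
    dat[[paste0(m, "_x")]] <- r * cos(alpha)
    dat[[paste0(m, "_y")]] <- r * sin(alpha)
    dat[[paste0(m, "_z")]] <- rep(CLUB_Z[[if (m == "CLUB_GRIP") "grip" else "head"]], n)
  }

  if (profile$noise_sd_m > 0) {
    withr::with_seed(seed, {
      for (cc in marker_cols()) {
        dat[[cc]] <- dat[[cc]] + rnorm(n, sd = profile$noise_sd_m)
      }
    })
  }

  # analytic ground truth on the noiseless series
  speed <- CLUB_RADII[["head"]] * abs(rate)
  vx <- -CLUB_RADII[["head"]] * rate * sin(alpha)
  start_frame <- which(speed >= 0.2 & vx < 0)[1]
  top_frame <- round(t_top * fs) + 1L
  impact_frame <- round(t_imp * fs) + 1L
  sep <- th_deg - pe_deg
  xfac <- sep[top_frame]
  truth <- list(
    events = list(start_frame = start_frame, top_frame = top_frame,
                  impact_frame = impact_frame),
    parameters = tibble(
      tmax_deg = abs(th_deg[top_frame] - th_deg[start_frame]),
      pmax_deg = abs(pe_deg[top_frame] - pe_deg[start_frame]),
      xfac_deg = xfac,
      sxfac_deg = max(0, max(sep[top_frame:impact_frame]) - xfac),
      gcv_mps = max(speed[(top_frame + 1):impact_frame])
    )
  )
  out <- swing_trial(dat, participant_id, trial_index, fs)
  attr(out, "ground_truth") <- truth
  out
}

#' Sex-specific simulation presets
#'
#' Between-player means and SDs of the swing parameters for female and
#' male junior players (pelvis amplitude, thorax amplitude, club-head
#' speed), plus the pelvis onset lag: males begin the backswing with the
#' thorax and the pelvis follows (~40 ms here), females start both
#' segments together. The lag values are simulator parameters, not
#' measured quantities.
#'
#' @param sex `"F"` or `"M"`.
#' @return a list of `mean`/`sd` pairs per parameter.
#' @export
sex_preset <- function(sex) {
  if (!is.character(sex) || length(sex) != 1 || !sex %in% c("F", "M")) {
    abort("sex must be \"F\" or \"M\"")
  }
  if (sex == "F") {
    list(sex = "F",
         pmax = list(mean = 46.80, sd = 6.44),
         tmax = list(mean = 110.57, sd = 7.21),
         gcv  = list(mean = 23.01, sd = 1.34),
         pelvis_onset_lag = list(mean = 0.000, sd = 0.004))
  } else {
    list(sex = "M",
         pmax = list(mean = 38.96, sd = 8.44),
         tmax = list(mean = 111.34, sd = 17.51),
         gcv  = list(mean = 27.31, sd = 1.99),
         pelvis_onset_lag = list(mean = 0.040, sd = 0.008))
  }
}

#' Generate a full synthetic cohort
#'
#' Player-level profiles are seeded normal draws from the [sex_preset()]
#' distributions (amplitudes and speeds truncated at zero); within-player
#' trial-to-trial jitter is 20% of the between-player SD. Swing-phase
#' durations vary mildly between players.
#'
#' @param n_female,n_male number of players per sex.
#' @param trials_per_player trials recorded per player.
#' @param seed integer seed (required).
#' @param noise_sd_m marker noise SD passed to every trial.
#' @return a [swing_cohort()] whose `truth` element tabulates per-trial
#'   ground-truth parameters and the player-level profile draws.
#' @export
generate_cohort <- function(n_female = 8, n_male = 6, trials_per_player = 10,
                            seed, noise_sd_m = 0.002) {
  stopifnot(n_female >= 1, n_male >= 1, trials_per_player >= 1)
  if (missing(seed) || is.null(seed)) abort("generate_cohort requires a seed")

  sexes <- c(rep("F", n_female), rep("M", n_male))
  ids <- sprintf("%s%02d", sexes, c(seq_len(n_female), seq_len(n_male)))
  participants <- tibble(participant_id = ids, sex = sexes)

  trials <- list()
  truth_rows <- list()
  withr::with_seed(seed, {
    for (i in seq_along(ids)) {
      ps <- sex_preset(sexes[i])
      player <- list(
        pmax = max(rnorm(1, ps$pmax$mean, ps$pmax$sd), 0),
        tmax = max(rnorm(1, ps$tmax$mean, ps$tmax$sd), 0),
        gcv  = max(rnorm(1, ps$gcv$mean, ps$gcv$sd), 0.5),
        lag  = max(rnorm(1, ps$pelvis_onset_lag$mean, ps$pelvis_onset_lag$sd), 0),
        backswing = min(max(rnorm(1, 0.90, 0.05), 0.70), 1.10),
        downswing = min(max(rnorm(1, 0.32, 0.03), 0.25), 0.45),
        lead = max(rnorm(1, 0.020, 0.008), 0),
        follow = min(max(rnorm(1, 0.60, 0.05), 0.40), 0.80)
      )
      for (k in seq_len(trials_per_player)) {
        prof <- swing_profile(
          pmax_deg = max(player$pmax + rnorm(1, 0, 0.2 * ps$pmax$sd), 0),
          tmax_deg = max(player$tmax + rnorm(1, 0, 0.2 * ps$tmax$sd), 0),
          gcv_mps  = max(player$gcv + rnorm(1, 0, 0.2 * ps$gcv$sd), 0.5),
          pelvis_onset_lag = player$lag,
          transition_lead = player$lead,
          follow_frac = player$follow,
          backswing_duration = player$backswing,
          downswing_duration = player$downswing,
          noise_sd_m = noise_sd_m
        )
        tr <- generate_trial(prof, ids[i], k,
                             seed = sample.int(.Machine$integer.max, 1))
        trials[[length(trials) + 1]] <- tr
        gt <- ground_truth(tr)
        truth_rows[[length(truth_rows) + 1]] <- dplyr::bind_cols(
          tibble(participant_id = ids[i], trial_index = k, sex = sexes[i],
                 player_pmax = player$pmax, player_tmax = player$tmax,
                 player_gcv = player$gcv, pelvis_onset_lag = player$lag,
                 start_frame = gt$events$start_frame,
                 top_frame = gt$events$top_frame,
                 impact_frame = gt$events$impact_frame),
          gt$parameters
        )
      }
    }
  })
  out <- swing_cohort(participants, trials)
  out$truth <- bind_rows(truth_rows)
  out
}
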